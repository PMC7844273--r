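# Shared fixtures and independent oracles, built in code.

mcin <- function() muraenesox_annotation(quiet = TRUE)

canon <- function() canonical_vertebrate_order()

## tiny single-PCG annotation on a linear coordinate system
mini_pcg_annotation <- function(seqs, strands = NULL, stops = NULL,
                                starts = NULL, gap = 2L) {
  n <- length(seqs)
  if (is.null(strands)) strands <- rep("H", n)
  if (is.null(stops)) stops <- rep("TAA", n)
  if (is.null(starts)) starts <- rep("ATG", n)
  lens <- nchar(seqs)
  start <- integer(n); end <- integer(n)
  pos <- 1L
  pieces <- character(n)
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + lens[i] - 1L
    pieces[i] <- if (strands[i] == "L") revcomp(seqs[i]) else seqs[i]
    pos <- end[i] + gap + 1L
  }
  genome_length <- end[n] + gap
  filler <- strrep("A", gap)
  genome <- paste0(paste0(pieces, filler, collapse = ""))
  ann <- mito_annotation(
    data.frame(name = paste0("G", seq_len(n)), class = "PCG",
               start = start, end = end, strand = strands,
               start_codon = starts, stop_codon = stops,
               anticodon = NA_character_, stringsAsFactors = FALSE),
    genome_length = genome_length, circular = TRUE, quiet = TRUE)
  list(ann = ann, seq = genome)
}

## independent brute-force oracle for single TDRL events: every circular
## window up to max_len and every loss assignment (copy1/copy2/both; both
## only for labels in `both_ok`). A window lacking a duplicated label
## cannot produce the extra copy, so such windows are skipped (each label
## occurs at most twice in the result and only window labels duplicate).
brute_force_one_event <- function(obs, ref, max_len = 8L,
                                  both_ok = function(u) grepl("^CR", u)) {
  lab <- ref$labels
  n <- length(lab)
  dup_needed <- length(obs$labels) - n
  hits <- list()
  for (p in 1:n) {
    for (L in 2:min(max_len, n - 1L)) {
      idx <- ((p - 1L) + 0:(L - 1L)) %% n + 1L
      W <- lab[idx]
      W_u <- sub("^-", "", W)
      can_dup <- both_ok(W_u)
      if (sum(can_dup) < dup_needed) next
      choices <- lapply(seq_along(W_u), function(i)
        if (can_dup[i]) c("1", "2", "b") else c("1", "2"))
      grid <- expand.grid(choices, stringsAsFactors = FALSE)
      for (g in seq_len(nrow(grid))) {
        a <- unlist(grid[g, ], use.names = FALSE)
        if (sum(a == "b") != dup_needed) next
        k1 <- W_u[a %in% c("1", "b")]
        k2 <- W_u[a %in% c("2", "b")]
        if (length(k1) == 0L || length(k2) == 0L) next
        res <- apply_tdrl(ref, tdrl_event(W, k1, k2))
        if (order_identical(res, obs)) {
          hits[[length(hits) + 1L]] <- list(window = W, kept1 = k1, kept2 = k2)
        }
      }
    }
  }
  hits
}

## random gene order with unique labels; optionally a CR element at the end
random_order <- function(n, with_cr = FALSE) {
  labs <- paste0("g", seq_len(n))
  signs <- sample(c("", "-"), n, replace = TRUE)
  toks <- paste0(signs, labs)
  if (with_cr) toks <- c(toks, "CR")
  gene_order(toks, circular = TRUE)
}

## random valid TDRL event on ord
random_event <- function(ord, max_len = 5L, allow_cr_both = TRUE) {
  lab <- ord$labels
  n <- length(lab)
  L <- sample(2:min(max_len, n - 1L), 1L)
  p <- sample(n, 1L)
  idx <- ((p - 1L) + 0:(L - 1L)) %% n + 1L
  W <- lab[idx]
  W_u <- sub("^-", "", W)
  repeat {
    a <- sample(c("1", "2"), L, replace = TRUE)
    cr_i <- which(grepl("^CR", W_u))
    if (allow_cr_both && length(cr_i) > 0L && stats::runif(1) < 0.5) {
      a[cr_i] <- "b"
    }
    if (any(a %in% c("1", "b")) && any(a %in% c("2", "b"))) break
  }
  tdrl_event(W, W_u[a %in% c("1", "b")], W_u[a %in% c("2", "b")])
}

## circular-arrangement equality modulo copy-suffix numbering of duplicated
## labels (CR1/CR2 from different scenarios may swap suffixes)
arrangements_equal <- function(a, b, ref) {
  to_base <- function(o) gene_order(mitorearr:::obs_in_ref_space(o, ref),
                                    circular = o$circular)
  order_identical(to_base(a), to_base(b))
}
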