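# Synthetic annotated mitogenomes: sequence + feature table + ground truth,
# so geometry, composition, codon and rearrangement operations are testable
# without downloads. The default configuration is a structural twin of the
# M. cinereus mitogenome: canonical vertebrate gene template, the
# six-element TDRL event applied, published gene lengths and junction gaps,
# total length 17,673 nt.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

default_gene_lengths <- function() {
  c(F = 72, `12S` = 962, V = 70, `16S` = 1706, L1 = 76, ND1 = 969, I = 72,
    Q = 71, M = 70, ND2 = 1044, W = 70, A = 69, N = 73, OL = 39, C = 66,
    Y = 71, COI = 1603, S1 = 71, D = 68, COII = 691, K = 75, ATP8 = 168,
    ATP6 = 684, COIII = 786, G = 70, ND3 = 351, R = 70, ND4L = 297,
    ND4 = 1381, H = 69, S2 = 71, L2 = 72, ND5 = 1857, Cytb = 1140, T = 72,
    CR1 = 902, ND6 = 516, E = 69, P = 77, CR2 = 944, CR = 944)
}

## junction gaps (nt) keyed "upstream|downstream" on unsigned labels;
## unlisted junctions default to 0 (abutting). Values follow the published
## coordinates, including the overlaps (negative gaps).
default_spacer_plan <- function() {
  c("ND1|I" = 7, "Q|M" = -1, "ND2|W" = -2, "W|A" = 1, "A|N" = 1,
    "OL|C" = 11, "Y|COI" = 1, "S1|D" = 5, "D|COII" = 3, "K|ATP8" = 1,
    "ATP8|ATP6" = -10, "ATP6|COIII" = -1, "COIII|G" = -1, "ND3|R" = -2,
    "ND4L|ND4" = -7, "ND5|Cytb" = 35, "Cytb|T" = 4, "ND6|E" = 1,
    "E|P" = 23)
}

## start/stop codons per PCG. COI's published length (1603 nt) is only
## frame-consistent with an incomplete stop, so the synthetic twin gives it
## T- (the printed table's "TAA" is flagged by the validator instead).
default_pcg_codons <- function() {
  list(
    ND1 = c("ATG", "TAA"), ND2 = c("ATG", "TAG"), COI = c("GTG", "T-"),
    COII = c("ATG", "T-"), ATP8 = c("ATG", "TAA"), ATP6 = c("ATG", "TAA"),
    COIII = c("ATG", "TAA"), ND3 = c("ATG", "TAG"), ND4L = c("ATG", "TAA"),
    ND4 = c("ATG", "T-"), ND5 = c("ATG", "TAA"), Cytb = c("ATG", "AGA"),
    ND6 = c("ATG", "AGG"))
}

#' Configuration for synthetic mitogenome generation
#'
#' Defaults emulate the M. cinereus mitogenome: the canonical vertebrate
#' gene template with the six-element TDRL event applied, published gene
#' lengths and junction gaps (genome length 17,673 nt), genome-wide base
#' probabilities matching the published composition, and a uniform sense
#' codon bias. One global seed drives a single pseudo-random stream.
#'
#' @param genome_length Optional expected genome length; an error is raised
#'   if the laid-out features do not produce it.
#' @param base_probs Named probabilities (`A`, `C`, `G`, `T`) for i.i.d.
#'   background/non-coding sequence; must sum to 1 (tolerance 1e-9).
#' @param gene_template A `gene_order` to start from.
#' @param gene_lengths Named lengths (nt) per token (fallback to the base
#'   label for suffixed copies).
#' @param spacer_plan Named junction gaps, keys `"upstream|downstream"` on
#'   unsigned labels; may be negative (overlap). Unlisted junctions are 0.
#' @param tdrl_events List of [tdrl_event]s applied to the template before
#'   layout.
#' @param codon_bias Named weights over sense codons (default uniform).
#' @param pcg_codons List mapping PCG label to `c(start, stop)` codon.
#' @param seed Integer seed.
#' @return An object of class `synthesis_config`.
#' @export
synthesis_config <- function(genome_length = NULL,
                             base_probs = c(A = 32.1, C = 23.8, G = 16.6, T = 27.6) / 100.1,
                             gene_template = canonical_vertebrate_order(),
                             gene_lengths = default_gene_lengths(),
                             spacer_plan = default_spacer_plan(),
                             tdrl_events = list(muraenesox_tdrl_event()),
                             codon_bias = NULL,
                             pcg_codons = default_pcg_codons(),
                             seed = 1L) {
  stopifnot(all(c("A", "C", "G", "T") %in% names(base_probs)))
  if (abs(sum(base_probs) - 1) > 1e-9) stop("base_probs must sum to 1")
  if (any(base_probs < 0)) stop("base_probs must be non-negative")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  if (is.null(codon_bias)) {
    codon_bias <- stats::setNames(rep(1, length(SENSE_CODONS)), SENSE_CODONS)
  }
  bad <- setdiff(names(codon_bias), SENSE_CODONS)
  if (length(bad) > 0L) {
    stop("codon_bias must be over sense codons only; offending: ",
         paste(bad, collapse = ", "))
  }
  structure(list(genome_length = genome_length, base_probs = base_probs,
                 gene_template = gene_template, gene_lengths = gene_lengths,
                 spacer_plan = spacer_plan, tdrl_events = tdrl_events,
                 codon_bias = codon_bias, pcg_codons = pcg_codons,
                 seed = as.integer(seed)),
            class = "synthesis_config")
}

lookup_length <- function(lab, lengths) {
  if (!is.null(lengths[[lab]])) return(as.integer(lengths[[lab]]))
  base <- sub("[0-9]+$", "", lab)
  if (!is.null(lengths[[base]]) && base != lab) return(as.integer(lengths[[base]]))
  stop("no length configured for gene ", lab)
}

## genome positions of a feature's coding sequence, 5'->3' on its strand
coding_positions <- function(start, end, genome_length, strand) {
  pos <- if (end >= start) start:end else c(start:genome_length, 1:end)
  if (strand == "L") rev(pos) else pos
}

#' Synthesize an annotated mitogenome
#'
#' Applies the configured TDRL events to the gene template, lays features
#' out with the configured lengths and junction gaps, and emits sequence:
#' background drawn i.i.d. from `base_probs`, `TACAT`/`ATGTA` motifs
#' planted in every control region, and protein-coding genes filled with
#' their annotated start codon, in-frame sense codons drawn from
#' `codon_bias`, and their annotated (possibly incomplete) stop codon.
#' L-strand genes are written reverse-complemented in genome space. Where
#' PCGs overlap, later genes are drawn subject to the bases already fixed,
#' and draws avoid creating spurious in-frame stop codons in any
#' overlapping frame, so the recorded ground-truth codons are exact.
#' Deterministic given the seed.
#'
#' @param cfg A [synthesis_config].
#' @return An object of class `synthetic_mitogenome`: list with `sequence`
#'   (character scalar), `annotation` ([mito_annotation]), `ground_truth`
#'   (true order, events, per-gene codons, codon counts, per-class
#'   composition, motif positions) and `config`.
#' @export
synthesize <- function(cfg) {
  stopifnot(inherits(cfg, "synthesis_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  ord <- cfg$gene_template
  for (e in cfg$tdrl_events) ord <- apply_tdrl(ord, e)
  labs <- tok_label(ord$labels)
  strands <- tok_strand(ord$labels)
  n <- length(labs)

  lens <- vapply(labs, lookup_length, integer(1L), lengths = cfg$gene_lengths)
  gaps <- vapply(seq_len(n), function(i) {
    key <- paste(labs[i], labs[(i %% n) + 1L], sep = "|")
    as.integer(cfg$spacer_plan[key] %||% NA_integer_)
  }, integer(1L))
  gaps[is.na(gaps)] <- 0L

  start <- integer(n); end <- integer(n)
  start[1L] <- 1L
  end[1L] <- lens[1L]
  for (i in 2:n) {
    start[i] <- end[i - 1L] + gaps[i - 1L] + 1L
    if (start[i] < 1L) stop("layout error: feature ", labs[i], " starts before position 1")
    end[i] <- start[i] + lens[i] - 1L
  }
  genome_length <- end[n] + gaps[n]
  if (!is.null(cfg$genome_length) && cfg$genome_length != genome_length) {
    stop("configured genome_length ", cfg$genome_length,
         " inconsistent with laid-out length ", genome_length)
  }

  classes <- token_class(labs)
  feats <- data.frame(
    name = token_to_name(labs), class = classes, start = start, end = end,
    strand = strands,
    start_codon = NA_character_, stop_codon = NA_character_,
    anticodon = NA_character_, stringsAsFactors = FALSE)
  for (i in which(classes == "PCG")) {
    cods <- cfg$pcg_codons[[labs[i]]]
    if (is.null(cods)) stop("no start/stop codons configured for PCG ", labs[i])
    feats$start_codon[i] <- cods[1L]
    feats$stop_codon[i] <- cods[2L]
  }

  # --- sequence assembly -------------------------------------------------
  chars <- sample(c("A", "C", "G", "T"), genome_length, replace = TRUE,
                  prob = cfg$base_probs[c("A", "C", "G", "T")])
  fixed <- logical(genome_length)

  motif_positions <- NULL
  for (i in which(classes == "CR")) {
    if (lens[i] >= 40L) {
      for (m in list(c("TACAT", 10L), c("ATGTA", 30L))) {
        at <- start[i] + as.integer(m[2L]) - 1L
        mseq <- strsplit(m[1L], "")[[1L]]
        chars[at:(at + 4L)] <- mseq
        motif_positions <- rbind(motif_positions, data.frame(
          region = labs[i], motif = m[1L], position = at,
          stringsAsFactors = FALSE))
      }
    }
  }

  pcg_idx <- which(classes == "PCG")
  cp_list <- lapply(pcg_idx, function(i)
    coding_positions(start[i], end[i], genome_length, strands[i]))
  names(cp_list) <- labs[pcg_idx]
  trailing <- vapply(pcg_idx, function(i) {
    switch(normalize_stop(feats$stop_codon[i]), "T-" = 1L, "TA-" = 2L, 0L)
  }, integer(1L))
  n_cod <- (lens[pcg_idx] - trailing) %/% 3L
  if (any((lens[pcg_idx] - trailing) %% 3L != 0L)) {
    stop("PCG length(s) not frame-consistent with configured stop codons: ",
         paste(labs[pcg_idx][(lens[pcg_idx] - trailing) %% 3L != 0L], collapse = ", "))
  }
  complete_stop <- trailing == 0L

  write_coding <- function(pos, coding_chars, strand) {
    out <- if (strand == "L") unname(COMPLEMENT[coding_chars]) else coding_chars
    conflict <- fixed[pos] & chars[pos] != out
    if (any(conflict)) {
      stop("config error: conflicting fixed bases at position(s) ",
           paste(pos[conflict], collapse = ", "))
    }
    chars[pos] <<- out
    fixed[pos] <<- TRUE
  }

  # stamp start and stop anchors first so overlapping genes respect them
  for (k in seq_along(pcg_idx)) {
    i <- pcg_idx[k]
    cp <- cp_list[[k]]
    sc <- strsplit(feats$start_codon[i], "")[[1L]]
    write_coding(cp[1:3], sc, strands[i])
    stop_cod <- normalize_stop(feats$stop_codon[i])
    stop_chars <- strsplit(sub("-", "", stop_cod), "")[[1L]]
    tail_pos <- cp[(lens[i] - length(stop_chars) + 1L):lens[i]]
    write_coding(tail_pos, stop_chars, strands[i])
  }

  # sense codon draws, genome order. Codons whose positions touch another
  # PCG or an anchor go through a constrained path with cross-frame stop
  # avoidance; the rest are drawn in bulk.
  coverage <- integer(genome_length)
  for (cp in cp_list) coverage[cp] <- coverage[cp] + 1L
  per_gene <- vector("list", length(pcg_idx))
  names(per_gene) <- labs[pcg_idx]
  bias <- cfg$codon_bias
  bias_w <- bias[SENSE_CODONS]
  bias_w[is.na(bias_w)] <- 0
  codon_chars <- strsplit(SENSE_CODONS, "")
  names(codon_chars) <- SENSE_CODONS
  for (k in seq_along(pcg_idx)) {
    i <- pcg_idx[k]
    cp <- cp_list[[k]]
    sense_range <- seq.int(2L, n_cod[k] - as.integer(complete_stop[k]))
    drawn <- character(length(sense_range))
    pos_mat <- rbind(cp[3L * sense_range - 2L], cp[3L * sense_range - 1L],
                     cp[3L * sense_range])
    constrained <- fixed[pos_mat[1L, ]] | fixed[pos_mat[2L, ]] |
      fixed[pos_mat[3L, ]] |
      coverage[pos_mat[1L, ]] > 1L | coverage[pos_mat[2L, ]] > 1L |
      coverage[pos_mat[3L, ]] > 1L
    free <- which(!constrained)
    if (length(free) > 0L) {
      drawn[free] <- sample(SENSE_CODONS, length(free), replace = TRUE,
                            prob = bias_w)
      free_pos <- as.vector(pos_mat[, free])
      free_chars <- unlist(codon_chars[drawn[free]], use.names = FALSE)
      if (strands[i] == "L") free_chars <- unname(COMPLEMENT[free_chars])
      chars[free_pos] <- free_chars
      fixed[free_pos] <- TRUE
    }
    for (si in which(constrained)) {
      pos <- pos_mat[, si]
      pat <- ifelse(fixed[pos],
                    if (strands[i] == "L") unname(COMPLEMENT[chars[pos]]) else chars[pos],
                    NA_character_)
      cands <- SENSE_CODONS
      for (b in 1:3) {
        if (!is.na(pat[b])) cands <- cands[substr(cands, b, b) == pat[b]]
      }
      if (length(cands) == 0L) {
        stop("no sense codon compatible with fixed bases in ", labs[i])
      }
      ok <- vapply(cands, function(cand) {
        !creates_cross_frame_stop(cand, pos, strands[i], k, pcg_idx, cp_list,
                                  n_cod, complete_stop, chars, fixed, strands)
      }, logical(1L))
      if (any(ok)) cands <- cands[ok]
      w <- bias[cands]
      w[is.na(w)] <- 0
      if (sum(w) == 0) w <- rep(1, length(cands))
      choice <- if (length(cands) == 1L) cands else
        sample(cands, 1L, prob = w)
      drawn[si] <- choice
      write_coding(pos, codon_chars[[choice]], strands[i])
    }
    stop_rec <- if (complete_stop[k]) feats$stop_codon[i] else NULL
    per_gene[[k]] <- c(feats$start_codon[i], drawn, stop_rec)
  }

  seq_str <- paste(chars, collapse = "")
  ann <- mito_annotation(feats, genome_length = genome_length,
                         circular = TRUE, organism = "synthetic mitogenome",
                         accession = "SYNTHETIC", quiet = TRUE)

  all_codons <- unlist(per_gene, use.names = FALSE)
  starts <- vapply(per_gene, function(x) x[1L], character(1L))
  gt_counts <- codon_usage(table(factor(all_codons, levels = ALL_CODONS)),
                           start_codons = starts)

  count_region <- function(rows) {
    cc <- chars[unlist(lapply(rows, function(i) start[i]:end[i]))]
    c(A = sum(cc == "A"), C = sum(cc == "C"),
      G = sum(cc == "G"), T = sum(cc == "T"))
  }
  regions <- c(as.list(stats::setNames(seq_len(n), labs)),
               lapply(split(seq_len(n), classes), identity))
  true_comp <- lapply(regions, count_region)
  true_comp$genome <- c(A = sum(chars == "A"), C = sum(chars == "C"),
                        G = sum(chars == "G"), T = sum(chars == "T"))

  structure(list(
    sequence = seq_str,
    annotation = ann,
    ground_truth = list(
      true_order = ord,
      true_events = cfg$tdrl_events,
      true_codon_counts = gt_counts,
      per_gene_codons = per_gene,
      true_composition = true_comp,
      motif_positions = motif_positions,
      spacer_plan = stats::setNames(gaps, paste(labs, labs[c(2:n, 1L)], sep = "|"))),
    config = cfg), class = "synthetic_mitogenome")
}

## would writing `cand` at genome positions `pos` complete a stop codon in
## another overlapping PCG's reading frame?
creates_cross_frame_stop <- function(cand, pos, strand, k, pcg_idx, cp_list,
                                     n_cod, complete_stop, chars, fixed,
                                     strands) {
  cand_chars <- strsplit(cand, "")[[1L]]
  genome_chars <- if (strand == "L") unname(COMPLEMENT[cand_chars]) else cand_chars
  for (h in seq_along(pcg_idx)) {
    if (h == k) next
    cp_h <- cp_list[[h]]
    j <- match(pos, cp_h)
    if (all(is.na(j))) next
    tris <- unique((j[!is.na(j)] - 1L) %/% 3L + 1L)
    # only sense codon positions of the other gene matter
    tris <- tris[tris >= 2L & tris <= n_cod[h] - as.integer(complete_stop[h])]
    for (tj in tris) {
      tp <- cp_h[(3L * tj - 2L):(3L * tj)]
      tri <- character(3L)
      known <- logical(3L)
      for (b in 1:3) {
        hit <- match(tp[b], pos)
        if (!is.na(hit)) {
          tri[b] <- genome_chars[hit]; known[b] <- TRUE
        } else if (fixed[tp[b]]) {
          tri[b] <- chars[tp[b]]; known[b] <- TRUE
        }
      }
      if (all(known)) {
        h_strand <- strands[pcg_idx[h]]
        coding_tri <- if (h_strand == "L") unname(COMPLEMENT[tri]) else tri
        if (paste(coding_tri, collapse = "") %in% STOP_CODONS) return(TRUE)
      }
    }
  }
  FALSE
}

#' @export
print.synthetic_mitogenome <- function(x, ...) {
  cat(sprintf("Synthetic mitogenome: %d nt, %d features, seed %d\n",
              x$annotation$genome_length, nrow(x$annotation$features),
              x$config$seed))
  invisible(x)
}

#' Write a synthetic mitogenome to disk
#'
#' Emits FASTA sequence, the feature table in the package TSV dialect, and
#' a JSON ground-truth sidecar.
#'
#' @param x A `synthetic_mitogenome`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(x, dir, prefix = "synthetic") {
  stopifnot(inherits(x, "synthetic_mitogenome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, ".fasta"))
  dna <- Biostrings::DNAStringSet(x$sequence)
  names(dna) <- paste0(prefix, " synthetic mitogenome")
  Biostrings::writeXStringSet(dna, fa)
  tsv <- file.path(dir, paste0(prefix, "_features.tsv"))
  write_feature_table(x$annotation, tsv)
  js <- file.path(dir, paste0(prefix, "_truth.json"))
  gt <- x$ground_truth
  payload <- list(
    true_order = gt$true_order$labels,
    true_events = lapply(gt$true_events, function(e)
      list(window = e$window, kept_in_copy1 = e$kept1, kept_in_copy2 = e$kept2)),
    true_codon_counts = as.list(gt$true_codon_counts$counts),
    true_composition = gt$true_composition,
    motif_positions = gt$motif_positions,
    seed = x$config$seed)
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, features = tsv, truth = js))
}

#' Apply a single labelled perturbation to a gene order
#'
#' Positive/negative controls for [compare_orders()] and
#' [adjudicate_models()]: translocate a block, invert a block in place, or
#' duplicate an element. The perturbation performed is recorded in the
#' `perturbation` attribute of the result.
#'
#' @param order A `gene_order`.
#' @param op One of `"translocate"`, `"invert"`, `"duplicate"`.
#' @param block Character vector of signed tokens (contiguous in `order`)
#'   for translocate/invert; a single unsigned label for duplicate. When
#'   `NULL`, a random block/label is chosen (seeded).
#' @param after Unsigned label after which the block/copy is inserted
#'   (translocate/duplicate).
#' @param seed Optional seed for random choices.
#' @return The perturbed `gene_order`.
#' @export
perturb_order <- function(order, op = c("translocate", "invert", "duplicate"),
                          block = NULL, after = NULL, seed = NULL) {
  op <- match.arg(op)
  stopifnot(inherits(order, "gene_order"))
  if (!is.null(seed)) set.seed(seed)
  lab <- order$labels
  n <- length(lab)
  u <- tok_label(lab)
  if (is.null(block)) {
    if (op == "duplicate") {
      block <- sample(u, 1L)
    } else {
      s <- sample(1:3, 1L)
      p <- sample(n - s + 1L, 1L)
      block <- lab[p:(p + s - 1L)]
    }
  }
  locate_block <- function(b) {
    L <- length(b)
    for (p in 1:n) {
      idx <- ((p - 1L) + 0:(L - 1L)) %% n + 1L
      if (!order$circular && any(diff(idx) != 1L)) next
      if (identical(lab[idx], b)) return(idx)
    }
    stop("block not found in order: ", paste(b, collapse = ","))
  }
  if (op == "invert") {
    idx <- locate_block(block)
    flipped <- make_tok(tok_label(rev(block)),
                        ifelse(tok_strand(rev(block)) == "H", "L", "H"))
    lab[idx] <- flipped
    res <- gene_order(lab, circular = order$circular)
  } else if (op == "translocate") {
    if (is.null(after)) stop("translocate needs an 'after' label")
    idx <- locate_block(block)
    rest <- lab[-idx]
    at <- which(tok_label(rest) == after)
    if (length(at) == 0L) stop("insertion label not found: ", after)
    at <- at[1L]
    res <- gene_order(append(rest, block, after = at),
                      circular = order$circular)
  } else {
    at0 <- which(u == block)
    if (length(at0) == 0L) stop("label not found: ", block)
    at0 <- at0[1L]
    tok <- lab[at0]
    after <- after %||% u[n]
    lab[at0] <- make_tok(paste0(block, "1"), tok_strand(tok))
    at <- which(tok_label(lab) == after | tok_label(lab) == paste0(block, "1") &
                  after == block)
    at <- at[length(at)]
    res <- gene_order(append(lab, make_tok(paste0(block, "2"), tok_strand(tok)),
                             after = at), circular = order$circular)
  }
  attr(res, "perturbation") <- list(op = op, block = block, after = after)
  res
}
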