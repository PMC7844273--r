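# Circular signed gene orders: extraction from annotations, the canonical
# vertebrate arrangement, rotation-aware comparison and rearrangement calls,
# and mapping a rearrangement character onto a phylogeny.

#' Construct a signed gene order
#'
#' A gene order is an ordered vector of signed gene tokens; a leading `-`
#' marks L-strand (light strand) encoding, unmarked tokens are H-strand.
#' Circular orders compare equal under rotation. Duplicate elements carry
#' numeric suffixes (`CR1`, `CR2`) so the token list is multiset-safe.
#'
#' @param labels Character vector of signed tokens, e.g.
#'   `c("ND5", "-ND6", "-E", "Cytb")`.
#' @param circular Logical; default `TRUE`.
#' @return An object of class `gene_order`.
#' @export
gene_order <- function(labels, circular = TRUE) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("gene order must be non-empty")
  structure(list(labels = labels, circular = isTRUE(circular)),
            class = "gene_order")
}

#' @export
print.gene_order <- function(x, ...) {
  cat(sprintf("%s gene order, %d tokens:\n",
              if (x$circular) "Circular" else "Linear", length(x$labels)))
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.gene_order <- function(x) length(x$labels)

#' Serialize / parse a gene order
#'
#' Orders are serialized as comma-separated signed tokens.
#'
#' @param x A `gene_order` (for `format_order`) or a string (for
#'   `parse_order`).
#' @param circular Circularity for the parsed order.
#' @return A string, or a `gene_order`.
#' @export
format_order <- function(x) paste(x$labels, collapse = ",")

#' @rdname format_order
#' @export
parse_order <- function(x, circular = TRUE) {
  gene_order(trimws(strsplit(x, ",", fixed = TRUE)[[1L]]), circular = circular)
}

#' Rotate a circular gene order
#'
#' @param x A `gene_order`.
#' @param k Number of positions to rotate left.
#' @return The rotated `gene_order`.
#' @export
rotate_order <- function(x, k) {
  stopifnot(inherits(x, "gene_order"))
  if (!x$circular && (k %% length(x$labels)) != 0L) {
    stop("cannot rotate a linear order")
  }
  gene_order(rotate_vec(x$labels, k), circular = x$circular)
}

#' Test equality of gene orders (rotation-invariant when circular)
#'
#' @param a,b `gene_order` objects.
#' @return Logical scalar.
#' @export
order_identical <- function(a, b) {
  stopifnot(inherits(a, "gene_order"), inherits(b, "gene_order"))
  eq_circular(a$labels, b$labels, circular = a$circular && b$circular)
}

eq_circular <- function(a, b, circular = TRUE) {
  if (length(a) != length(b)) return(FALSE)
  if (!circular) return(identical(a, b))
  for (k in 0:(length(a) - 1L)) {
    if (identical(rotate_vec(a, k), b)) return(TRUE)
  }
  FALSE
}

#' The canonical vertebrate mitochondrial gene order
#'
#' The typical vertebrate arrangement as a 39-token circular signed order,
#' starting at trnF by convention and including the light-strand replication
#' origin (OL) and the control region (CR) as tokens. ND6 and the bound trnE
#' sit between ND5 and Cytb, on the light strand.
#'
#' @return A `gene_order` of 39 tokens.
#' @export
canonical_vertebrate_order <- function() {
  gene_order(c(
    "F", "12S", "V", "16S", "L1", "ND1", "I", "-Q", "M", "ND2", "W", "-A",
    "-N", "OL", "-C", "-Y", "COI", "-S1", "D", "COII", "K", "ATP8", "ATP6",
    "COIII", "G", "ND3", "R", "ND4L", "ND4", "H", "S2", "L2", "ND5", "-ND6",
    "-E", "Cytb", "T", "-P", "CR"
  ), circular = TRUE)
}

## feature name -> order token ("trnF" -> "F"); everything else verbatim
name_to_token <- function(name) sub("^trn", "", name)
token_to_name <- function(token) {
  trna <- token_class(token) == "tRNA"
  ifelse(trna, paste0("trn", token), token)
}

## classify an (unsigned, possibly suffixed) token
token_class <- function(token) {
  base <- sub("[0-9]+$", "", token)
  trna_tokens <- c("F", "V", "L", "I", "Q", "M", "W", "A", "N", "C", "Y",
                   "S", "D", "K", "G", "R", "H", "T", "E", "P")
  ifelse(token %in% c("12S", "16S"), "rRNA",
  ifelse(base == "CR", "CR",
  ifelse(base == "OL", "OL",
  ifelse(base %in% trna_tokens & nchar(token) <= 2L, "tRNA", "PCG"))))
}

#' Extract the signed gene order of an annotation
#'
#' Tokens are emitted in ascending start order with strand signs; tRNA names
#' are shortened (`trnF` -> `F`). OL and CR are included as tokens (control
#' regions behave as mobile elements in rearranged mitogenomes); set
#' `include_trna = FALSE` for a tRNA-free "major gene" order for cross-study
#' comparison.
#'
#' @param ann A [mito_annotation].
#' @param include_trna Keep tRNA tokens (default `TRUE`).
#' @return A `gene_order`.
#' @export
extract_order <- function(ann, include_trna = TRUE) {
  stopifnot(inherits(ann, "mito_annotation"))
  f <- ann$features
  if (!include_trna) f <- f[f$class != "tRNA", , drop = FALSE]
  gene_order(make_tok(name_to_token(f$name), f$strand), circular = ann$circular)
}

#' Compare a gene order against a reference
#'
#' Finds the most parsimonious description of the observed order as the
#' reference plus moved blocks, duplications and losses. Duplicate labels
#' (`CR1`/`CR2`) are matched to their reference element greedily by context
#' similarity; the copy whose neighbours match the reference context is
#' treated as the resident element and the others as duplicates. The
#' comparison is rotation-invariant; it anchors at the reference's first
#' token (conventionally trnF), and ties between equally small moved blocks
#' are broken lexicographically (C locale) on the signed block labels.
#'
#' @param obs,ref `gene_order` objects. Label multisets may differ only by
#'   duplications and losses.
#' @return An object of class `rearrangement_call`: list with `kind`
#'   (subset of `identical`, `shuffling`, `translocation`, `inversion`,
#'   `duplication`, `complex`), `moved_blocks` (each with `block`,
#'   `old_context`, `new_context`, `type`), `duplicated`, `lost`,
#'   `duplicate_mapping`, and the reduced aligned orders used internally.
#' @export
compare_orders <- function(obs, ref) {
  stopifnot(inherits(obs, "gene_order"), inherits(ref, "gene_order"))
  circular <- obs$circular && ref$circular
  ref_l <- ref$labels
  ref_u <- tok_label(ref_l)

  obs_u_raw <- tok_label(obs$labels)
  obs_base <- base_label(obs_u_raw, ref_u)
  obs_signed <- make_tok(obs_base, tok_strand(obs$labels))

  if (length(intersect(obs_base, ref_u)) == 0L) {
    stop("cannot compare orders with disjoint label sets")
  }

  obs_counts <- table(obs_base)
  ref_counts <- table(ref_u)
  all_lab <- union(names(obs_counts), names(ref_counts))
  oc <- stats::setNames(rep(0L, length(all_lab)), all_lab)
  rc <- oc
  oc[names(obs_counts)] <- as.integer(obs_counts)
  rc[names(ref_counts)] <- as.integer(ref_counts)
  duplicated_labels <- all_lab[oc > rc]
  lost <- rep(all_lab[rc > oc], times = (rc - oc)[rc > oc])
  extra_in_obs <- setdiff(obs_base, ref_u)
  if (length(extra_in_obs) > 0L) {
    stop("observed order contains label(s) absent from the reference: ",
         paste(unique(extra_in_obs), collapse = ", "))
  }

  # resolve duplicated labels: keep the copy whose obs context matches the
  # reference context; surplus copies are the duplicates
  n_obs <- length(obs_signed)
  dup_positions <- integer(0)
  dup_map <- NULL
  for (lab in duplicated_labels) {
    pos <- which(obs_base == lab)
    ref_pos <- which(ref_u == lab)[1L]
    ref_nb <- c(ref_u[((ref_pos - 2L) %% length(ref_u)) + 1L],
                ref_u[(ref_pos %% length(ref_u)) + 1L])
    score <- vapply(pos, function(p) {
      nb <- c(obs_base[((p - 2L) %% n_obs) + 1L],
              obs_base[(p %% n_obs) + 1L])
      sum(nb == ref_nb)
    }, integer(1L))
    keep_n <- rc[[lab]]
    ord <- order(-score, pos)
    kept <- pos[ord][seq_len(keep_n)]
    dropped <- setdiff(pos, kept)
    dup_positions <- c(dup_positions, dropped)
    amb <- keep_n < length(pos) &&
      length(unique(score)) == 1L && length(pos) > 1L
    dup_map <- rbind(dup_map, data.frame(
      label = obs$labels[pos], base = lab, position = pos,
      context_score = score, kept_as_reference = pos %in% kept,
      ambiguous = amb, stringsAsFactors = FALSE))
  }

  red_obs <- obs_signed[setdiff(seq_len(n_obs), dup_positions)]
  red_ref <- ref_l
  for (lab in unique(lost)) {
    drop_n <- sum(lost == lab)
    at <- which(tok_label(red_ref) == lab)
    red_ref <- red_ref[-utils::tail(at, drop_n)]
  }

  # anchor rotation at the reference's first token
  if (circular) {
    anchor <- tok_label(red_ref[1L])
    hit <- which(tok_label(red_obs) == anchor)
    if (length(hit) > 0L) red_obs <- rotate_vec(red_obs, hit[1L] - 1L)
  }

  call <- list(duplicated = duplicated_labels, lost = unique(lost),
               duplicate_mapping = dup_map,
               reduced_obs = red_obs, reduced_ref = red_ref)

  if (eq_circular(red_obs, red_ref, circular)) {
    call$moved_blocks <- list()
    call$kind <- if (length(duplicated_labels) == 0L && length(lost) == 0L) {
      "identical"
    } else {
      c(if (length(duplicated_labels) > 0L) "duplication",
        if (length(lost) > 0L) "complex")
    }
    class(call) <- "rearrangement_call"
    return(call)
  }

  blk <- find_single_moved_block(red_obs, red_ref, circular)
  if (!is.null(blk)) {
    info <- classify_block(blk, red_obs, red_ref)
    call$moved_blocks <- list(info)
    kinds <- info$type
    if (length(duplicated_labels) > 0L) kinds <- c(kinds, "duplication")
    if (length(lost) > 0L) kinds <- c(kinds, "complex")
    call$kind <- unique(kinds)
  } else {
    call$moved_blocks <- lcs_moved_blocks(red_obs, red_ref)
    kinds <- "complex"
    if (length(duplicated_labels) > 0L) kinds <- c(kinds, "duplication")
    call$kind <- kinds
  }
  class(call) <- "rearrangement_call"
  call
}

## smallest contiguous obs block whose removal makes obs and ref (minus the
## same labels) identical up to rotation; ties broken lexicographically
find_single_moved_block <- function(obs, ref, circular) {
  n <- length(obs)
  for (s in 1:(n - 2L)) {
    cands <- list()
    p_range <- if (circular) 1:n else 1:(n - s + 1L)
    for (p in p_range) {
      idx <- ((p - 1L) + 0:(s - 1L)) %% n + 1L
      if (!circular && any(diff(idx) != 1L)) next
      rem_obs <- obs[-idx]
      block_u <- tok_label(obs[idx])
      rem_ref <- ref
      drop <- match(block_u, tok_label(rem_ref))
      if (anyNA(drop)) next
      rem_ref <- rem_ref[-drop]
      if (eq_circular(rem_obs, rem_ref, circular)) {
        cands[[length(cands) + 1L]] <- list(idx = idx, block = obs[idx])
      }
    }
    if (length(cands) > 0L) {
      best <- cands[[1L]]
      for (c2 in cands[-1L]) {
        if (clex_cmp(c2$block, best$block) < 0L) best <- c2
      }
      return(best)
    }
  }
  NULL
}

classify_block <- function(blk, obs, ref) {
  n <- length(obs)
  idx <- blk$idx
  block <- blk$block
  block_u <- tok_label(block)
  ref_u <- tok_label(ref)
  ref_pos <- match(block_u, ref_u)
  obs_prev <- obs[((idx[1L] - 2L) %% n) + 1L]
  obs_next <- obs[(idx[length(idx)] %% n) + 1L]
  m <- length(ref)
  ref_prev <- ref[((min(ref_pos) - 2L) %% m) + 1L]
  ref_next <- ref[(max(ref_pos) %% m) + 1L]

  contiguous <- length(ref_pos) == 1L ||
    all(diff(sort(ref_pos)) == 1L)
  same_sign <- all(tok_strand(block) == tok_strand(ref[ref_pos]))
  signs_flipped <- all(tok_strand(block) != tok_strand(ref[ref_pos]))
  order_same <- !is.unsorted(ref_pos)
  order_reversed <- !is.unsorted(rev(ref_pos))

  type <- if (contiguous && signs_flipped && (length(block) == 1L || order_reversed)) {
    "inversion"
  } else if (contiguous && same_sign && order_same) {
    # shuffling: a lone tRNA displaced locally; otherwise a translocation
    displacement <- min(abs(idx[1L] - min(ref_pos)),
                        n - abs(idx[1L] - min(ref_pos)))
    if (length(block) == 1L && token_class(block_u) == "tRNA" && displacement <= 2L) {
      "shuffling"
    } else "translocation"
  } else {
    "complex"
  }
  list(block = block, old_context = c(ref_prev, ref_next),
       new_context = c(obs_prev, obs_next), type = type)
}

## fallback for multi-block rearrangements: tokens off the longest common
## subsequence, grouped into contiguous runs
lcs_moved_blocks <- function(obs, ref) {
  keep <- lcs_keep(obs, ref)
  moved <- which(!keep)
  if (length(moved) == 0L) return(list())
  runs <- split(moved, cumsum(c(1L, diff(moved) != 1L)))
  lapply(runs, function(idx) {
    n <- length(obs)
    list(block = obs[idx],
         old_context = c(NA_character_, NA_character_),
         new_context = c(obs[((idx[1L] - 2L) %% n) + 1L],
                         obs[(idx[length(idx)] %% n) + 1L]),
         type = "complex")
  })
}

## logical vector over obs: membership in one longest common subsequence
lcs_keep <- function(obs, ref) {
  n <- length(obs); m <- length(ref)
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- if (obs[i] == ref[j]) d[i, j] + 1L else
        max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  keep <- logical(n)
  i <- n; j <- m
  while (i > 0L && j > 0L) {
    if (obs[i] == ref[j] && d[i + 1L, j + 1L] == d[i, j] + 1L) {
      keep[i] <- TRUE; i <- i - 1L; j <- j - 1L
    } else if (d[i, j + 1L] >= d[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  keep
}

#' @export
print.rearrangement_call <- function(x, ...) {
  cat("Rearrangement call:", paste(x$kind, collapse = "+"), "\n")
  for (b in x$moved_blocks) {
    cat(sprintf("  %s block (%s): ref context (%s | %s) -> new context (%s | %s)\n",
                b$type, paste(b$block, collapse = ","),
                b$old_context[1L], b$old_context[2L],
                b$new_context[1L], b$new_context[2L]))
  }
  if (length(x$duplicated) > 0L) {
    cat("  duplicated:", paste(x$duplicated, collapse = ", "), "\n")
  }
  if (length(x$lost) > 0L) {
    cat("  lost:", paste(x$lost, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map a binary rearrangement character onto a tree
#'
#' Given a rooted tree and a per-tip state (e.g. `rearranged` vs
#' `canonical`), reports whether each state's tips form a clade
#' (monophyly), and for each state the smallest clade containing all its
#' tips.
#'
#' @param tree A newick string or an `ape` `phylo` object (treated as
#'   rooted as given).
#' @param states Named character vector mapping every tip label to a state.
#' @return An object of class `monophyly_report`: per state, the tips, a
#'   `monophyletic` flag, and the tip set of the smallest containing clade.
#' @export
map_character_on_tree <- function(tree, states) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  if (is.null(phy)) stop("could not parse tree")
  unknown <- setdiff(names(states), phy$tip.label)
  if (length(unknown) > 0L) {
    stop("state(s) given for unknown tip(s): ", paste(unknown, collapse = ", "))
  }
  missing_tips <- setdiff(phy$tip.label, names(states))
  if (length(missing_tips) > 0L) {
    stop("no state for tip(s): ", paste(missing_tips, collapse = ", "))
  }
  out <- list()
  for (s in unique(states)) {
    tips <- names(states)[states == s]
    mono <- ape::is.monophyletic(phy, tips)
    clade_tips <- if (length(tips) == 1L) {
      tips
    } else if (length(tips) == length(phy$tip.label)) {
      phy$tip.label
    } else {
      mrca <- ape::getMRCA(phy, tips)
      ape::extract.clade(phy, mrca)$tip.label
    }
    out[[s]] <- list(state = s, tips = tips, monophyletic = mono,
                     smallest_clade = clade_tips)
  }
  structure(out, class = "monophyly_report")
}

#' @export
print.monophyly_report <- function(x, ...) {
  for (s in x) {
    cat(sprintf("state '%s': %d tip(s), monophyletic: %s (smallest clade: %d tips)\n",
                s$state, length(s$tips), s$monophyletic, length(s$smallest_clade)))
  }
  invisible(x)
}
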