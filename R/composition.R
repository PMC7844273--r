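# Base composition, A+T content, AT/GC skew, and motif scanning.

#' Construct a base composition
#'
#' Holds A/C/G/T counts and/or percentages for a region. Skews are defined
#' on either representation: `AT skew = (A - T)/(A + T)` and
#' `GC skew = (G - C)/(G + C)` give identical values from counts and from
#' the corresponding percentages.
#'
#' @param counts Named numeric vector with elements `A`, `C`, `G`, `T`
#'   (ambiguity codes are not counted here; pass their number via
#'   `n_ambiguous`).
#' @param percentages Named numeric vector with elements `A`, `C`, `G`, `T`
#'   summing to ~100. Supply counts, percentages, or both.
#' @param region_label Free-text label for the region.
#' @param n_ambiguous Number of excluded ambiguous bases (N etc.).
#' @return An object of class `base_composition`.
#' @examples
#' base_composition(percentages = c(A = 44.6, T = 14.1, C = 28.3, G = 13.0))
#' @export
base_composition <- function(counts = NULL, percentages = NULL,
                             region_label = "", n_ambiguous = 0L) {
  if (is.null(counts) && is.null(percentages)) {
    stop("supply counts and/or percentages")
  }
  bases <- c("A", "C", "G", "T")
  if (!is.null(counts)) {
    stopifnot(all(bases %in% names(counts)))
    counts <- counts[bases]
    if (any(counts < 0)) stop("negative base counts")
    if (is.null(percentages) && sum(counts) > 0) {
      percentages <- 100 * counts / sum(counts)
    }
  }
  if (!is.null(percentages)) {
    stopifnot(all(bases %in% names(percentages)))
    percentages <- percentages[bases]
    if (any(percentages < 0) || any(percentages > 100)) {
      stop("percentages must lie in [0, 100]")
    }
  }
  structure(list(counts = counts, percentages = percentages,
                 region_label = region_label, n_ambiguous = n_ambiguous),
            class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf("Base composition%s\n",
              if (nzchar(x$region_label)) paste0(" [", x$region_label, "]") else ""))
  if (!is.null(x$counts)) {
    cat("  counts:     ", paste(sprintf("%s=%d", names(x$counts),
                                        as.integer(x$counts)), collapse = " "),
        sprintf(" (total %d)\n", as.integer(sum(x$counts))))
  }
  if (!is.null(x$percentages)) {
    cat("  percent:    ", paste(sprintf("%s=%.1f", names(x$percentages),
                                        x$percentages), collapse = " "), "\n")
    cat(sprintf("  A+T%%: %.1f  AT-skew: %.3f  GC-skew: %.3f\n",
                x$percentages[["A"]] + x$percentages[["T"]],
                at_skew(x), gc_skew(x)))
  }
  invisible(x)
}

comp_values <- function(c) {
  if (!is.null(c$counts)) c$counts else c$percentages
}

#' AT skew
#'
#' `(A - T)/(A + T)`, a strand-asymmetry statistic in \[-1, 1\]. Positive
#' values mean an excess of adenine over thymine on the counted strand.
#'
#' @param c A [base_composition] (counts or percentages).
#' @return Numeric scalar in \[-1, 1\], at full precision (round only for
#'   display).
#' @examples
#' at_skew(base_composition(percentages = c(A = 44.6, T = 14.1, C = 28.3, G = 13)))
#' @export
at_skew <- function(c) {
  stopifnot(inherits(c, "base_composition"))
  v <- comp_values(c)
  denom <- v[["A"]] + v[["T"]]
  if (denom == 0) stop("AT skew undefined: A + T = 0")
  unname((v[["A"]] - v[["T"]]) / denom)
}

#' GC skew
#'
#' `(G - C)/(G + C)`; negative values mean an excess of cytosine over
#' guanine on the counted strand.
#'
#' @inheritParams at_skew
#' @return Numeric scalar in \[-1, 1\].
#' @export
gc_skew <- function(c) {
  stopifnot(inherits(c, "base_composition"))
  v <- comp_values(c)
  denom <- v[["G"]] + v[["C"]]
  if (denom == 0) stop("GC skew undefined: G + C = 0")
  unname((v[["G"]] - v[["C"]]) / denom)
}

#' Base composition of an annotated region
#'
#' Counts bases over the slice(s) of the genome covered by a named feature,
#' a feature class (`PCG`, `tRNA`, `rRNA`, `CR`, `OL`; multi-feature classes
#' concatenate slices), or the whole `"genome"`. By default slices are taken
#' on the H strand regardless of coding strand, which is how per-gene
#' composition tables for mitogenomes are conventionally reported; set
#' `strand = "coding"` to reverse-complement L-strand features first.
#' Ambiguity codes are excluded from the four counts and tallied separately.
#'
#' @param seq Nucleotide string of length `ann$genome_length`.
#' @param ann A [mito_annotation].
#' @param region Feature name, feature class, or `"genome"`.
#' @param strand `"H"` (default) or `"coding"`.
#' @return A [base_composition] with counts and percentages.
#' @export
region_composition <- function(seq, ann, region, strand = c("H", "coding")) {
  strand <- match.arg(strand)
  stopifnot(inherits(ann, "mito_annotation"))
  seq <- toupper(seq)
  if (nchar(seq) != ann$genome_length) {
    stop("sequence length ", nchar(seq), " differs from genome length ",
         ann$genome_length)
  }
  f <- ann$features
  if (identical(region, "genome")) {
    pieces <- seq
  } else if (region %in% f$name) {
    rows <- which(f$name == region)
    pieces <- extract_slices(seq, f[rows, , drop = FALSE], strand)
  } else if (region %in% f$class) {
    rows <- which(f$class == region)
    pieces <- extract_slices(seq, f[rows, , drop = FALSE], strand)
  } else {
    stop("unknown region: ", region)
  }
  chars <- strsplit(paste(pieces, collapse = ""), "", fixed = TRUE)[[1L]]
  counts <- c(A = sum(chars == "A"), C = sum(chars == "C"),
              G = sum(chars == "G"), T = sum(chars == "T"))
  n_amb <- length(chars) - sum(counts)
  base_composition(counts = counts, region_label = region, n_ambiguous = n_amb)
}

extract_slices <- function(seq, rows, strand) {
  vapply(seq_len(nrow(rows)), function(i) {
    s <- circular_substr(seq, rows$start[i], rows$end[i])
    if (strand == "coding" && rows$strand[i] == "L") s <- revcomp(s)
    s
  }, character(1L))
}

#' Scan a sequence for short motifs
#'
#' Finds all (possibly overlapping) occurrences of each motif on the given
#' strand, reporting 1-based start positions on the input sequence. The
#' palindromic pair `TACAT`/`ATGTA`, associated with termination of
#' heavy-strand replication in control regions, is the default.
#'
#' @param seq Nucleotide string.
#' @param motifs Character vector of uppercase ACGT motifs.
#' @param strand `"H"` to scan the given strand, `"both"` to also scan the
#'   reverse complement (positions still reported on the input strand).
#' @return A data.frame with columns `motif`, `position`, `strand`, ordered
#'   by position; zero rows when nothing is found.
#' @examples
#' motif_scan("TACATGTA")  # overlapping hits at 1 and 4
#' @export
motif_scan <- function(seq, motifs = c("TACAT", "ATGTA"),
                       strand = c("H", "both")) {
  strand <- match.arg(strand)
  if (length(motifs) == 0L) stop("motifs must be non-empty")
  if (any(grepl("[^ACGT]", motifs))) {
    stop("motifs must contain only A, C, G, T: ",
         paste(motifs[grepl("[^ACGT]", motifs)], collapse = ", "))
  }
  seq <- toupper(seq)
  scan_one <- function(s, m, str_label) {
    hits <- gregexpr(paste0("(?=", m, ")"), s, perl = TRUE)[[1L]]
    if (hits[1L] == -1L) return(NULL)
    data.frame(motif = m, position = as.integer(hits), strand = str_label,
               stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in motifs) {
    out[[length(out) + 1L]] <- scan_one(seq, m, "H")
    if (strand == "both") {
      rc_hits <- scan_one(revcomp(seq), m, "L")
      if (!is.null(rc_hits)) {
        # map positions back to the input strand (start of the motif's
        # reverse-complement image)
        rc_hits$position <- nchar(seq) - (rc_hits$position + nchar(m) - 1L) + 1L
        out[[length(out) + 1L]] <- rc_hits
      }
    }
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  if (length(out) == 0L) {
    return(data.frame(motif = character(0), position = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$position, res$motif), , drop = FALSE]
}
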