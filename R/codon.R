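# Codon counting, amino-acid frequencies and RSCU under the vertebrate
# mitochondrial genetic code (NCBI transl_table 2: AGA/AGG are stops,
# ATA is Met, TGA is Trp).

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

vertebrate_mito_code <- function() {
  code <- c(
    TTT = "Phe", TTC = "Phe", TTA = "Leu", TTG = "Leu",
    CTT = "Leu", CTC = "Leu", CTA = "Leu", CTG = "Leu",
    ATT = "Ile", ATC = "Ile", ATA = "Met", ATG = "Met",
    GTT = "Val", GTC = "Val", GTA = "Val", GTG = "Val",
    TCT = "Ser", TCC = "Ser", TCA = "Ser", TCG = "Ser",
    CCT = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
    ACT = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
    GCT = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
    TAT = "Tyr", TAC = "Tyr", TAA = "Stp", TAG = "Stp",
    CAT = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
    AAT = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
    GAT = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
    TGT = "Cys", TGC = "Cys", TGA = "Trp", TGG = "Trp",
    CGT = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
    AGT = "Ser", AGC = "Ser", AGA = "Stp", AGG = "Stp",
    GGT = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly"
  )
  code[ALL_CODONS]
}

MITO_CODE <- vertebrate_mito_code()
SENSE_CODONS <- names(MITO_CODE)[MITO_CODE != "Stp"]
STOP_CODONS <- names(MITO_CODE)[MITO_CODE == "Stp"]

#' Count codons over the protein-coding genes of an annotation
#'
#' Each PCG is extracted on its coding strand (L-strand genes are
#' reverse-complemented), trailing incomplete-stop nucleotides (`T-`: 1 nt,
#' `TA-`: 2 nt) are dropped, and codons are read in frame from the annotated
#' start. A gene whose trimmed length is not divisible by 3 triggers a frame
#' warning and is skipped (and listed in the result).
#'
#' @param ann A [mito_annotation].
#' @param seq Nucleotide string of length `ann$genome_length`.
#' @param exclude Optional character vector of PCG names to leave out (e.g.
#'   `"ND6"` for workflows that drop it).
#' @return An object of class `codon_usage`: list with `counts` (named
#'   integer vector over the 64 codons), `n_codons`, `genetic_code`,
#'   `start_codon_usage` (table of first codons, one per gene),
#'   `per_gene` (list of codon vectors), and `skipped`.
#' @export
count_codons <- function(ann, seq, exclude = character(0)) {
  stopifnot(inherits(ann, "mito_annotation"))
  seq <- toupper(seq)
  if (nchar(seq) != ann$genome_length) {
    stop("sequence length ", nchar(seq), " differs from genome length ",
         ann$genome_length)
  }
  f <- ann$features
  rows <- which(f$class == "PCG" & !(f$name %in% exclude))
  per_gene <- list()
  skipped <- character(0)
  for (i in rows) {
    s <- circular_substr(seq, f$start[i], f$end[i])
    if (f$strand[i] == "L") s <- revcomp(s)
    trailing <- 0L
    if (!is.na(f$stop_codon[i])) {
      sc <- normalize_stop(f$stop_codon[i])
      trailing <- switch(sc, "T-" = 1L, "TA-" = 2L, 0L)
    }
    len <- nchar(s) - trailing
    if (len %% 3L != 0L) {
      warning(sprintf("PCG %s: trimmed length %d not divisible by 3; gene skipped",
                      f$name[i], len), call. = FALSE)
      skipped <- c(skipped, f$name[i])
      next
    }
    body <- substr(s, 1L, len)
    per_gene[[f$name[i]]] <- substring(body, seq(1L, len, 3L), seq(3L, len, 3L))
  }
  all_codons <- unlist(per_gene, use.names = FALSE)
  counts <- table(factor(all_codons, levels = ALL_CODONS))
  counts <- stats::setNames(as.integer(counts), ALL_CODONS)
  starts <- vapply(per_gene, function(x) x[1L], character(1L))
  structure(list(counts = counts, n_codons = sum(counts),
                 genetic_code = "vertebrate mitochondrial",
                 start_codon_usage = table(starts),
                 per_gene = per_gene, skipped = skipped),
            class = "codon_usage")
}

#' Build a codon usage object from raw counts
#'
#' @param counts Named integer vector of codon counts (missing codons are
#'   taken as zero).
#' @param start_codons Optional character vector of gene-initial codons
#'   (used by [aa_frequencies()] to count non-ATG starts as Met).
#' @return A `codon_usage` object.
#' @export
codon_usage <- function(counts, start_codons = character(0)) {
  full <- stats::setNames(integer(64L), ALL_CODONS)
  bad <- setdiff(names(counts), ALL_CODONS)
  if (length(bad) > 0L) stop("unknown codon(s): ", paste(bad, collapse = ", "))
  full[names(counts)] <- as.integer(counts)
  if (any(full < 0L)) stop("negative codon counts")
  structure(list(counts = full, n_codons = sum(full),
                 genetic_code = "vertebrate mitochondrial",
                 start_codon_usage = table(start_codons),
                 per_gene = NULL, skipped = character(0)),
            class = "codon_usage")
}

#' @export
print.codon_usage <- function(x, ...) {
  cat(sprintf("Codon usage (%s): %d codons over %d genes%s\n",
              x$genetic_code, x$n_codons,
              if (is.null(x$per_gene)) NA_integer_ else length(x$per_gene),
              if (length(x$skipped) > 0L)
                paste0("; skipped: ", paste(x$skipped, collapse = ", ")) else ""))
  invisible(x)
}

#' Relative synonymous codon usage
#'
#' For codon c of amino acid a with degeneracy d: `RSCU(c) = count(c) * d /
#' sum(counts over a's codons)`. Serine and leucine are each treated as a
#' single six-fold family (TCN+AGT/AGC and TTA/TTG+CTN), as the vertebrate
#' mitochondrial code implies. Families with zero total get RSCU 0 for all
#' their codons.
#'
#' @param u A `codon_usage`.
#' @param include_stops Also report the four-codon stop family (off by
#'   default).
#' @return Named numeric vector of RSCU values (64 codons, or 60 when stops
#'   are excluded).
#' @export
rscu <- function(u, include_stops = FALSE) {
  stopifnot(inherits(u, "codon_usage"))
  if (u$n_codons == 0L) stop("empty codon usage")
  code <- MITO_CODE
  keep <- if (include_stops) names(code) else names(code)[code != "Stp"]
  out <- stats::setNames(numeric(length(keep)), keep)
  for (aa in unique(code[keep])) {
    fam <- keep[code[keep] == aa]
    total <- sum(u$counts[fam])
    out[fam] <- if (total == 0) 0 else u$counts[fam] * length(fam) / total
  }
  out
}

#' Amino-acid frequencies
#'
#' Percentage of each amino acid among all non-stop codons. Stop-family
#' codons are excluded from the denominator; gene-initial codons other than
#' ATG (e.g. the GTG start of COI) are counted as Met, the convention used
#' by standard codon-usage software for mitogenomes.
#'
#' @param u A `codon_usage`.
#' @return Named numeric vector of percentages (sums to 100), sorted
#'   decreasing. Zero-usage input returns an empty vector with a warning.
#' @export
aa_frequencies <- function(u) {
  stopifnot(inherits(u, "codon_usage"))
  code <- MITO_CODE
  aa_counts <- tapply(u$counts, code[names(u$counts)], sum)
  aa_counts <- aa_counts[names(aa_counts) != "Stp"]
  # reassign non-ATG start codons to Met
  su <- u$start_codon_usage
  if (length(su) > 0L) {
    for (cod in names(su)) {
      if (cod != "ATG" && code[[cod]] != "Stp") {
        aa_counts[code[[cod]]] <- aa_counts[code[[cod]]] - su[[cod]]
        aa_counts["Met"] <- aa_counts["Met"] + su[[cod]]
      }
    }
  }
  total <- sum(aa_counts)
  if (total == 0) {
    warning("no non-stop codons counted", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  sort(100 * aa_counts / total, decreasing = TRUE)
}

#' Codon usage as a table
#'
#' @param u A `codon_usage`.
#' @param include_stops Include the stop family rows.
#' @return A data.frame with columns `codon`, `amino_acid`, `count`, `rscu`.
#' @export
codon_table <- function(u, include_stops = FALSE) {
  r <- rscu(u, include_stops = include_stops)
  data.frame(codon = names(r), amino_acid = unname(MITO_CODE[names(r)]),
             count = unname(u$counts[names(r)]), rscu = unname(r),
             stringsAsFactors = FALSE)
}
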