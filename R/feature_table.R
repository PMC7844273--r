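# Annotated circular mitogenome feature tables: parsing, validation and
# annotation geometry (gene lengths, intergenic spacers, stop codon classes).

FEATURE_CLASSES <- c("PCG", "tRNA", "rRNA", "CR", "OL")
STOP_TOKENS_COMPLETE <- c("TAA", "TAG", "AGA", "AGG")
STOP_TOKENS_INCOMPLETE <- c("T-", "TA-")

#' Construct a mitogenome annotation
#'
#' The central container of the package: a circular (by default) genome of
#' known length together with an ordered table of annotated features. Feature
#' coordinates are 1-based and inclusive on both ends, on the heavy (H)
#' strand, following the GenBank convention; light (L) strand features keep
#' H-strand coordinates and are reverse-complemented only when sequence is
#' extracted.
#'
#' @param features A data.frame with columns `name`, `class` (one of
#'   `r paste(FEATURE_CLASSES, collapse = ", ")`), `start`, `end`, `strand`
#'   (`H`/`L`), and optionally `start_codon`, `stop_codon`, `anticodon`
#'   (`NA` for absent). Extra columns are preserved.
#' @param genome_length Genome size in nucleotides. Defaults to `max(end)`.
#' @param circular Is the genome circular? Default `TRUE`.
#' @param organism,accession Free-text provenance labels.
#' @param quiet Suppress validation warnings (they are always recorded in
#'   the `validation` attribute).
#' @return An object of class `mito_annotation`: a list with elements
#'   `genome_length`, `circular`, `features` (sorted by start), `organism`,
#'   `accession`, and an attribute `validation` holding warning messages.
#' @export
mito_annotation <- function(features, genome_length = NULL, circular = TRUE,
                            organism = "", accession = "", quiet = FALSE) {
  required <- c("name", "class", "start", "end", "strand")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("start_codon", "stop_codon", "anticodon")) {
    if (!col %in% names(features)) features[[col]] <- NA_character_
  }
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  if (anyNA(features$start) || anyNA(features$end)) {
    stop("non-numeric start/end coordinate in feature table")
  }
  if (is.null(genome_length)) genome_length <- max(features$end)
  genome_length <- as.integer(genome_length)

  bad_class <- setdiff(unique(features$class), FEATURE_CLASSES)
  if (length(bad_class) > 0L) {
    stop("unknown feature class(es): ", paste(bad_class, collapse = ", "))
  }
  bad_strand <- setdiff(unique(features$strand), c("H", "L"))
  if (length(bad_strand) > 0L) {
    stop("strand must be 'H' or 'L', got: ", paste(bad_strand, collapse = ", "))
  }
  out_of_range <- features$start < 1L | features$start > genome_length |
    features$end < 1L | features$end > genome_length
  if (any(out_of_range)) {
    stop("feature(s) with coordinates outside [1, ", genome_length, "]: ",
         paste(features$name[out_of_range], collapse = ", "))
  }

  # disambiguate duplicated names with a numeric suffix in file order
  dup <- duplicated(features$name) | duplicated(features$name, fromLast = TRUE)
  if (any(dup)) {
    for (nm in unique(features$name[dup])) {
      idx <- which(features$name == nm)
      features$name[idx] <- paste0(nm, seq_along(idx))
    }
  }

  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL

  ann <- structure(
    list(genome_length = genome_length, circular = isTRUE(circular),
         features = features, organism = organism, accession = accession),
    class = "mito_annotation"
  )
  msgs <- validate_annotation(ann)
  attr(ann, "validation") <- msgs
  if (!quiet && length(msgs) > 0L) {
    for (m in msgs) warning(m, call. = FALSE)
  }
  ann
}

#' Validate annotation invariants
#'
#' Checks that printed lengths (if present) match coordinates, tRNA lengths
#' fall in the 60--100 nt range expected of mitochondrial tRNAs, and PCG
#' lengths are frame-consistent with their annotated stop codon (complete
#' stops leave a length divisible by 3; incomplete `T-`/`TA-` stops leave a
#' remainder of 1 or 2 nt). Violations are reported, never corrected.
#'
#' @param ann A [mito_annotation].
#' @return Character vector of messages (empty when all checks pass).
#' @export
validate_annotation <- function(ann) {
  f <- ann$features
  msgs <- character(0)
  len <- feature_length(f, ann$genome_length)
  if ("length_printed" %in% names(f)) {
    lp <- suppressWarnings(as.integer(f$length_printed))
    bad <- which(!is.na(lp) & lp != len)
    for (i in bad) {
      msgs <- c(msgs, sprintf(
        "feature %s: printed length %d differs from coordinate length %d",
        f$name[i], lp[i], len[i]))
    }
  }
  trna <- which(f$class == "tRNA")
  short_long <- trna[len[trna] < 60L | len[trna] > 100L]
  for (i in short_long) {
    msgs <- c(msgs, sprintf("tRNA %s has unusual length %d nt (expected 60-100)",
                            f$name[i], len[i]))
  }
  pcg <- which(f$class == "PCG" & !is.na(f$stop_codon))
  for (i in pcg) {
    stop_cod <- normalize_stop(f$stop_codon[i])
    trailing <- switch(stop_cod, "T-" = 1L, "TA-" = 2L, 0L)
    if ((len[i] - trailing) %% 3L != 0L) {
      msgs <- c(msgs, sprintf(
        "PCG %s: length %d nt is not frame-consistent with stop codon '%s'",
        f$name[i], len[i], f$stop_codon[i]))
    }
  }
  msgs
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf("Mitogenome annotation: %s%s\n",
              if (nzchar(x$organism)) paste0(x$organism, " ") else "",
              if (nzchar(x$accession)) paste0("(", x$accession, ")") else ""))
  cat(sprintf("  genome length: %d nt (%s)\n", x$genome_length,
              if (x$circular) "circular" else "linear"))
  tab <- table(factor(x$features$class, levels = FEATURE_CLASSES))
  cat(sprintf("  %d features: %s\n", nrow(x$features),
              paste(sprintf("%d %s", as.integer(tab), names(tab)), collapse = ", ")))
  v <- attr(x, "validation")
  if (length(v) > 0L) cat(sprintf("  %d validation note(s); see attr(., 'validation')\n", length(v)))
  invisible(x)
}

#' Read an annotated mitogenome feature table
#'
#' TSV dialect: UTF-8, header
#' `name class start end strand start_codon stop_codon anticodon`
#' with `.` for absent values; extra columns are carried along. The GenBank
#' flat-file reader maps `CDS`, `tRNA`, `rRNA`, `D-loop` and `rep_origin`
#' features onto the same model.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"genbank"`.
#' @inheritParams mito_annotation
#' @return A [mito_annotation].
#' @export
read_feature_table <- function(path, format = c("tsv", "genbank"),
                               genome_length = NULL, circular = TRUE,
                               organism = "", accession = "", quiet = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "genbank") {
    return(parse_genbank(path, circular = circular, quiet = quiet))
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, na.strings = ".",
                          quote = "", comment.char = "#")
  required <- c("name", "class", "start", "end", "strand")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  mito_annotation(df, genome_length = genome_length, circular = circular,
                  organism = organism, accession = accession, quiet = quiet)
}

#' Write a feature table in the package TSV dialect
#'
#' @param ann A [mito_annotation].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ann, path) {
  df <- ann$features
  df[] <- lapply(df, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "."
    col
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Minimal GenBank flat-file feature reader (CDS/tRNA/rRNA/D-loop/rep_origin).
## No offline GenBank parser ships with the R stack used here, so this covers
## exactly the subset of the format the package consumes.
parse_genbank <- function(path, circular = TRUE, quiet = FALSE) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  genome_length <- if (length(locus) > 0L) {
    as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1L]))
  } else NA_integer_
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  organism <- if (length(org) > 0L) trimws(sub("^\\s+ORGANISM\\s+", "", org[1L])) else ""
  acc <- grep("^ACCESSION", lines, value = TRUE)
  accession <- if (length(acc) > 0L) trimws(sub("^ACCESSION\\s+", "", acc[1L])) else ""

  feat_start <- grep("^FEATURES", lines)
  if (length(feat_start) == 0L) stop("no FEATURES block in ", path)
  end_block <- grep("^(ORIGIN|CONTIG|//)", lines)
  end_block <- end_block[end_block > feat_start[1L]]
  stop_at <- if (length(end_block) > 0L) end_block[1L] - 1L else length(lines)
  block <- lines[(feat_start[1L] + 1L):stop_at]

  key_map <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
               "D-loop" = "CR", rep_origin = "OL")
  is_key <- grepl("^ {5}\\S", block)
  idx <- which(is_key)
  feats <- list()
  for (k in seq_along(idx)) {
    first <- block[idx[k]]
    key <- sub("^ {5}(\\S+).*", "\\1", first)
    if (!key %in% names(key_map)) next
    loc <- trimws(sub("^ {5}\\S+\\s+", "", first))
    upto <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
    quals <- block[(idx[k] + 1L):upto]
    qual_text <- paste(trimws(quals), collapse = " ")
    strand <- if (grepl("complement", loc)) "L" else "H"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) < 2L) next
    start <- as.integer(nums[1L]); end <- as.integer(nums[length(nums)])
    get_qual <- function(q) {
      m <- regmatches(qual_text, regexec(paste0("/", q, '="?([^"/]+)"?'), qual_text))[[1L]]
      if (length(m) == 2L) trimws(m[2L]) else NA_character_
    }
    name <- get_qual("gene")
    if (is.na(name)) name <- get_qual("product")
    if (is.na(name)) name <- key
    feats[[length(feats) + 1L]] <- data.frame(
      name = name, class = unname(key_map[key]), start = start, end = end,
      strand = strand, start_codon = NA_character_, stop_codon = NA_character_,
      anticodon = get_qual("anticodon"), stringsAsFactors = FALSE)
  }
  if (length(feats) == 0L) stop("no mappable features found in ", path)
  df <- do.call(rbind, feats)
  if (is.na(genome_length)) genome_length <- max(df$end)
  mito_annotation(df, genome_length = genome_length, circular = circular,
                  organism = organism, accession = accession, quiet = quiet)
}

#' Feature length on a circular genome
#'
#' Linear features have length `end - start + 1`; wrap-around features
#' (`end < start`) have length `genome_length - start + 1 + end`.
#'
#' @param f A feature data.frame (rows of `ann$features`) or a
#'   [mito_annotation].
#' @param genome_length Genome size in nt (taken from `f` when it is an
#'   annotation).
#' @return Integer vector of lengths in nt.
#' @examples
#' feature_length(data.frame(start = 12034, end = 13890), 17673)  # ND5: 1857
#' @export
feature_length <- function(f, genome_length = NULL) {
  if (inherits(f, "mito_annotation")) {
    genome_length <- f$genome_length
    f <- f$features
  }
  stopifnot(!is.null(genome_length))
  ifelse(f$end >= f$start,
         f$end - f$start + 1L,
         genome_length - f$start + 1L + f$end)
}

normalize_stop <- function(stop) {
  s <- toupper(trimws(stop))
  s[s == "T"] <- "T-"
  s[s == "TA"] <- "TA-"
  s
}

#' Classify a stop codon as complete or incomplete
#'
#' Complete stops under the vertebrate mitochondrial code are `TAA`, `TAG`,
#' `AGA` and `AGG`; `T-` and `TA-` denote incomplete stops completed to
#' `TAA` by post-transcriptional polyadenylation. Bare `T`/`TA` are accepted
#' as synonyms of `T-`/`TA-`.
#'
#' @param stop Character vector of stop-codon tokens.
#' @return Character vector, `"complete"` or `"incomplete"`.
#' @examples
#' classify_stop_codon(c("TAA", "T-", "AGG"))
#' @export
classify_stop_codon <- function(stop) {
  s <- normalize_stop(stop)
  bad <- !(s %in% c(STOP_TOKENS_COMPLETE, STOP_TOKENS_INCOMPLETE))
  if (any(bad)) {
    stop("unknown stop codon token(s): ", paste(unique(stop[bad]), collapse = ", "))
  }
  ifelse(s %in% STOP_TOKENS_COMPLETE, "complete", "incomplete")
}

#' Intergenic spacers and overlaps
#'
#' For consecutive features i, i+1 in start order the gap is
#' `start[i+1] - end[i] - 1`: positive values are spacers, negative values
#' overlaps, zero abutting features. On circular genomes the final pair
#' wraps from the last feature back to the first. When the feature table
#' carries a printed intergenic column (`intergenic_printed`), the report
#' additionally reconciles computed gaps against it and flags junctions
#' where the two disagree.
#'
#' @param ann A [mito_annotation] with at least two features.
#' @param include_wrap Include the wrap-around junction (last feature to
#'   first) in the report. Defaults to the annotation's circularity.
#' @return An object of class `spacer_report`: list with `pairs` (data.frame
#'   `upstream`, `downstream`, `gap`), `total_spacer_nt`, `n_spacers`,
#'   `n_overlaps`, and, when a printed column is available,
#'   `printed_total_spacer_nt`, `printed_n_spacers` and `discrepancies`.
#' @export
intergenic_spacers <- function(ann, include_wrap = NULL) {
  stopifnot(inherits(ann, "mito_annotation"))
  f <- ann$features
  if (nrow(f) < 2L) stop("need at least two features to compute spacers")
  if (is.null(include_wrap)) include_wrap <- ann$circular

  up <- f$name[-nrow(f)]
  down <- f$name[-1L]
  gap <- f$start[-1L] - f$end[-nrow(f)] - 1L
  printed <- if ("intergenic_printed" %in% names(f)) {
    suppressWarnings(as.integer(f$intergenic_printed[-1L]))
  } else NULL

  if (include_wrap) {
    up <- c(up, f$name[nrow(f)])
    down <- c(down, f$name[1L])
    gap <- c(gap, ann$genome_length - f$end[nrow(f)] + f$start[1L] - 1L)
    # the printed column attributes each gap to its downstream feature, so
    # the first row's printed value belongs to the wrap junction
    if (!is.null(printed)) {
      printed <- c(printed, suppressWarnings(as.integer(f$intergenic_printed[1L])))
    }
  }
  pairs <- data.frame(upstream = up, downstream = down, gap = gap,
                      stringsAsFactors = FALSE)
  rep <- list(
    pairs = pairs,
    total_spacer_nt = sum(gap[gap > 0L]),
    n_spacers = sum(gap > 0L),
    n_overlaps = sum(gap < 0L)
  )
  if (!is.null(printed)) {
    pairs$printed <- printed
    rep$pairs <- pairs
    ok <- !is.na(printed)
    rep$printed_total_spacer_nt <- sum(printed[ok & printed > 0L])
    rep$printed_n_spacers <- sum(ok & printed > 0L)
    disc <- which(ok & printed != gap)
    rep$discrepancies <- pairs[disc, , drop = FALSE]
  }
  structure(rep, class = "spacer_report")
}

#' @export
print.spacer_report <- function(x, ...) {
  cat(sprintf("Spacer report: %d spacers totalling %d nt, %d overlaps\n",
              x$n_spacers, x$total_spacer_nt, x$n_overlaps))
  if (!is.null(x$printed_total_spacer_nt)) {
    cat(sprintf("  printed intergenic column: %d spacers totalling %d nt\n",
                x$printed_n_spacers, x$printed_total_spacer_nt))
    if (nrow(x$discrepancies) > 0L) {
      cat(sprintf("  %d junction(s) where printed and computed gaps disagree:\n",
                  nrow(x$discrepancies)))
      for (i in seq_len(nrow(x$discrepancies))) {
        d <- x$discrepancies[i, ]
        cat(sprintf("    %s -> %s: computed %d, printed %d\n",
                    d$upstream, d$downstream, d$gap, d$printed))
      }
    }
  }
  invisible(x)
}

#' The annotated mitogenome of Muraenesox cinereus (GenBank MT571331)
#'
#' Feature coordinates of the daggertooth pike conger mitogenome as
#' published for accession MT571331: 40 features (13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs, the light-strand replication origin, and two control
#' regions) on a 17,673 nt circular genome. The table carries the printed
#' length, amino-acid and intergenic columns alongside the coordinates;
#' known internal inconsistencies of the published table (the COI frame,
#' the OL/trnC junction) are surfaced as validation notes, not corrected.
#'
#' @param quiet Suppress validation warnings (default `TRUE`).
#' @return A [mito_annotation].
#' @export
muraenesox_annotation <- function(quiet = TRUE) {
  path <- system.file("extdata", "MT571331_features.tsv", package = "mitorearr",
                      mustWork = TRUE)
  read_feature_table(path, format = "tsv", genome_length = 17673L,
                     circular = TRUE, organism = "Muraenesox cinereus",
                     accession = "MT571331", quiet = quiet)
}

#' Published composition table of the Muraenesox cinereus mitogenome
#'
#' Base composition percentages, A+T content, skews and lengths per region
#' (whole mitogenome, each PCG, pooled tRNA/rRNA/control regions) as
#' published for accession MT571331.
#'
#' @return A data.frame with columns `region`, `pct_A`, `pct_T`, `pct_C`,
#'   `pct_G`, `pct_AT`, `at_skew_printed`, `gc_skew_printed`, `length_bp`.
#' @export
muraenesox_composition <- function() {
  path <- system.file("extdata", "MT571331_composition.tsv",
                      package = "mitorearr", mustWork = TRUE)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
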