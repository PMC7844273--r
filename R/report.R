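# End-to-end report bundles: the describe pipeline (geometry, composition,
# codon usage, motifs) and the rearrangement pipeline (order comparison,
# TDRL inference, model adjudication).

#' Describe a mitogenome: geometry, composition, codon usage, motifs
#'
#' Runs the characterisation pipeline over an annotation and (optionally) a
#' sequence. Sections that need the sequence are marked `skipped` when no
#' FASTA is given. Deterministic.
#'
#' @param annotation A [mito_annotation], or a path to a feature table.
#' @param fasta Optional genome sequence: a nucleotide string, or a path to
#'   a FASTA file (first record used).
#' @param format Annotation file format when `annotation` is a path.
#' @param circular Treat the genome as circular.
#' @param motifs Motifs scanned in control regions.
#' @return An object of class `mito_report`: list of sections `summary`,
#'   `geometry` (per-feature lengths and stop classes), `spacers`,
#'   `composition`, `codon_usage`, `rscu`, `aa_frequencies`, `motifs`;
#'   sequence-dependent sections are the string `"skipped"` without
#'   sequence.
#' @export
run_describe <- function(annotation, fasta = NULL, format = "tsv",
                         circular = TRUE, motifs = c("TACAT", "ATGTA")) {
  ann <- load_annotation(annotation, format, circular)
  seq <- load_sequence(fasta, ann)

  f <- ann$features
  geometry <- data.frame(
    name = f$name, class = f$class, start = f$start, end = f$end,
    strand = f$strand, length = feature_length(f, ann$genome_length),
    stringsAsFactors = FALSE)
  geometry$stop_class <- NA_character_
  has_stop <- f$class == "PCG" & !is.na(f$stop_codon)
  geometry$stop_class[has_stop] <- classify_stop_codon(f$stop_codon[has_stop])

  rep <- list(
    summary = list(organism = ann$organism, accession = ann$accession,
                   genome_length = ann$genome_length,
                   circular = ann$circular, n_features = nrow(f),
                   validation = attr(ann, "validation")),
    geometry = geometry,
    spacers = intergenic_spacers(ann))

  if (is.null(seq)) {
    rep$composition <- "skipped"
    rep$codon_usage <- "skipped"
    rep$rscu <- "skipped"
    rep$aa_frequencies <- "skipped"
    rep$motifs <- "skipped"
  } else {
    region_names <- c("genome", intersect(c("PCG", "tRNA", "rRNA", "CR"),
                                          unique(f$class)),
                      f$name[f$class == "PCG"])
    rep$composition <- do.call(rbind, lapply(region_names, function(rg) {
      comp <- region_composition(seq, ann, rg)
      p <- comp$percentages
      data.frame(region = rg, length = sum(comp$counts) + comp$n_ambiguous,
                 pct_A = p[["A"]], pct_T = p[["T"]], pct_C = p[["C"]],
                 pct_G = p[["G"]], pct_AT = p[["A"]] + p[["T"]],
                 at_skew = at_skew(comp), gc_skew = gc_skew(comp),
                 stringsAsFactors = FALSE)
    }))
    usage <- count_codons(ann, seq)
    rep$codon_usage <- usage
    rep$rscu <- codon_table(usage)
    rep$aa_frequencies <- aa_frequencies(usage)
    cr_rows <- which(f$class == "CR")
    hits <- lapply(cr_rows, function(i) {
      h <- motif_scan(circular_substr(seq, f$start[i], f$end[i]), motifs)
      if (nrow(h) > 0L) {
        h$region <- f$name[i]
        h$genome_position <- (f$start[i] + h$position - 2L) %% ann$genome_length + 1L
      }
      h
    })
    hits <- hits[vapply(hits, nrow, integer(1L)) > 0L]
    rep$motifs <- if (length(hits) > 0L) do.call(rbind, hits) else
      data.frame(motif = character(0), position = integer(0),
                 strand = character(0), region = character(0),
                 genome_position = integer(0))
  }
  structure(rep, class = "mito_report")
}

#' Analyse the rearrangement of a mitogenome gene order
#'
#' Extracts the gene order, compares it to the reference (canonical
#' vertebrate order by default), infers TDRL scenarios and adjudicates the
#' four rearrangement models, using the annotation's spacers as
#' duplication-remnant evidence.
#'
#' @param annotation A [mito_annotation] or a path to a feature table.
#' @param reference Reference `gene_order`.
#' @param format,circular As in [run_describe()].
#' @param max_events Search depth for [infer_tdrl()].
#' @return An object of class `rearrange_report`: list with `order`,
#'   `comparison`, `scenarios`, `adjudication`, `spacers`.
#' @export
run_rearrange <- function(annotation, reference = canonical_vertebrate_order(),
                          format = "tsv", circular = TRUE, max_events = 2L) {
  ann <- load_annotation(annotation, format, circular)
  obs <- extract_order(ann)
  spacers <- intergenic_spacers(ann)
  structure(list(
    order = obs,
    comparison = compare_orders(obs, reference),
    scenarios = infer_tdrl(obs, reference, max_events = max_events),
    adjudication = adjudicate_models(obs, reference, spacers = spacers,
                                     max_events = max_events),
    spacers = spacers), class = "rearrange_report")
}

load_annotation <- function(annotation, format, circular) {
  if (inherits(annotation, "mito_annotation")) return(annotation)
  read_feature_table(annotation, format = format, circular = circular,
                     quiet = TRUE)
}

load_sequence <- function(fasta, ann) {
  if (is.null(fasta)) return(NULL)
  seq <- if (file.exists(fasta) && !grepl("^[ACGTNacgtn]+$", fasta)) {
    as.character(Biostrings::readDNAStringSet(fasta)[[1L]])
  } else {
    fasta
  }
  toupper(seq)
}

#' @export
print.mito_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Mitogenome report: %s%s- %d nt, %d features\n",
              if (nzchar(s$organism)) paste0(s$organism, " ") else "",
              if (nzchar(s$accession)) paste0("(", s$accession, ") ") else "",
              s$genome_length, s$n_features))
  print(x$spacers)
  if (is.character(x$composition)) {
    cat("  composition/codon sections skipped (no sequence provided)\n")
  } else {
    cat(sprintf("  composition over %d regions; %d codons counted\n",
                nrow(x$composition), x$codon_usage$n_codons))
    aa <- utils::head(x$aa_frequencies, 3L)
    cat("  top amino acids:",
        paste(sprintf("%s %.2f%%", names(aa), aa), collapse = ", "), "\n")
    cat(sprintf("  %d control-region motif hit(s)\n",
                if (is.data.frame(x$motifs)) nrow(x$motifs) else 0L))
  }
  invisible(x)
}

#' @export
print.rearrange_report <- function(x, ...) {
  print(x$comparison)
  print(x$scenarios)
  print(x$adjudication)
  invisible(x)
}
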