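# Feature-table parsing, validation, and annotation geometry.

test_that("the published feature table parses with the expected census", {
  ann <- mcin()
  expect_s3_class(ann, "mito_annotation")
  expect_equal(ann$genome_length, 17673L)
  tab <- table(ann$features$class)
  expect_equal(as.integer(tab[c("PCG", "tRNA", "rRNA", "CR", "OL")]),
               c(13L, 22L, 2L, 2L, 1L))
  expect_equal(nrow(ann$features), 40L)
  # the published COI length is not frame-consistent with its complete
  # stop; that is surfaced as a validation note, never an error
  v <- attr(ann, "validation")
  expect_length(v, 1L)
  expect_match(v, "COI")
})

test_that("every printed length matches its coordinates", {
  ann <- mcin()
  f <- ann$features
  expect_equal(feature_length(f, ann$genome_length),
               as.integer(f$length_printed))
  expect_equal(feature_length(f[f$name == "ND5", ], ann$genome_length), 1857L)
  expect_equal(feature_length(f[f$name == "CR1", ], ann$genome_length), 902L)
})

test_that("feature_length handles degenerate and wrap-around coordinates", {
  expect_equal(feature_length(data.frame(start = 5, end = 5), 100), 1L)
  # wrap-around: positions 17670..17673 and 1..4, counted explicitly
  expect_equal(feature_length(data.frame(start = 17670, end = 4), 17673), 8L)
  expect_equal(feature_length(data.frame(start = 1, end = 50), 50), 50L)
})

test_that("validation rejects malformed tables", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tclass\tstart\tend", "x\tPCG\t1\t9"), tmp)
  expect_error(read_feature_table(tmp), "strand")
  expect_error(
    mito_annotation(data.frame(name = "x", class = "PCG", start = 1,
                               end = 200, strand = "H"),
                    genome_length = 100),
    "outside")
  expect_error(
    mito_annotation(data.frame(name = "x", class = "gene", start = 1,
                               end = 9, strand = "H"), genome_length = 10),
    "class")
})

test_that("a single feature spanning the genome is valid", {
  ann <- mito_annotation(
    data.frame(name = "CR", class = "CR", start = 1, end = 500, strand = "H"),
    genome_length = 500, quiet = TRUE)
  expect_equal(feature_length(ann), 500L)
})

test_that("stop codons classify as complete or incomplete", {
  expect_equal(classify_stop_codon(c("TAA", "TAG", "AGA", "AGG")),
               rep("complete", 4))
  expect_equal(classify_stop_codon(c("T-", "TA-", "T")), rep("incomplete", 3))
  expect_error(classify_stop_codon("TGA"), "unknown stop codon")
})

test_that("intergenic spacers follow coordinates and reconcile the printed column", {
  sp <- intergenic_spacers(mcin())
  # from coordinates: 12 positive gaps totalling 93 nt, 7 overlaps
  expect_equal(sp$n_spacers, 12L)
  expect_equal(sp$total_spacer_nt, 93L)
  expect_equal(sp$n_overlaps, 7L)
  # printed intergenic column: 12 positive gaps totalling 89 nt; the
  # disagreement is confined to the OL/trnC junction and flagged, never
  # silently corrected
  expect_equal(sp$printed_n_spacers, 12L)
  expect_equal(sp$printed_total_spacer_nt, 89L)
  expect_true(all(sp$discrepancies$downstream %in% c("OL", "trnC")))
  p <- sp$pairs
  expect_equal(p$gap[p$upstream == "ND5"], 35L)      # ND5 -> Cytb
  expect_equal(p$gap[p$upstream == "ATP8"], -10L)    # ATP8/ATP6 overlap
  expect_equal(p$gap[p$upstream == "CR2"], 0L)       # wrap junction
})

test_that("abutting features have zero gap", {
  ann <- mito_annotation(
    data.frame(name = c("a", "b"), class = "tRNA", start = c(1, 11),
               end = c(10, 20), strand = "H"),
    genome_length = 20, quiet = TRUE)
  sp <- intergenic_spacers(ann)
  expect_equal(sp$pairs$gap, c(0L, 0L))  # internal + wrap
  expect_equal(sp$n_spacers, 0L)
})

test_that("lengths plus gaps tile a circular genome exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    lens <- sample(60:90, 6L)
    gaps <- sample(0:9, 6L, replace = TRUE)
    start <- cumsum(c(1L, utils::head(lens + gaps, -1L)))
    ann <- mito_annotation(
      data.frame(name = paste0("t", 1:6), class = "tRNA", start = start,
                 end = start + lens - 1L, strand = "H"),
      genome_length = sum(lens) + sum(gaps), quiet = TRUE)
    sp <- intergenic_spacers(ann)
    expect_equal(sum(feature_length(ann)) + sum(sp$pairs$gap),
                 ann$genome_length)
  }
})

test_that("parse -> serialize -> parse round-trips", {
  ann <- mcin()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ann, tmp)
  ann2 <- read_feature_table(tmp, genome_length = 17673L,
                             organism = ann$organism,
                             accession = ann$accession, quiet = TRUE)
  expect_equal(ann2$features$name, ann$features$name)
  expect_equal(ann2$features$start, ann$features$start)
  expect_equal(ann2$features$end, ann$features$end)
  expect_equal(ann2$features$stop_codon, ann$features$stop_codon)
  expect_equal(ann2$genome_length, ann$genome_length)
})

test_that("the GenBank flat-file reader maps the standard feature keys", {
  gb <- c(
    "LOCUS       TESTMITO      300 bp    DNA     circular VRT 01-JAN-2020",
    "ACCESSION   TEST001",
    "  ORGANISM  Testus fishus",
    "FEATURES             Location/Qualifiers",
    "     tRNA            1..70",
    "                     /gene=\"trnF\"",
    "                     /anticodon=\"GAA\"",
    "     CDS             71..190",
    "                     /gene=\"ND1\"",
    "     rRNA            191..240",
    "                     /product=\"12S\"",
    "     tRNA            complement(241..260)",
    "                     /gene=\"trnQ\"",
    "     D-loop          261..290",
    "     rep_origin      291..300",
    "                     /note=\"OL\"",
    "ORIGIN",
    "//")
  tmp <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, tmp)
  ann <- read_feature_table(tmp, format = "genbank", quiet = TRUE)
  expect_equal(ann$genome_length, 300L)
  expect_equal(ann$organism, "Testus fishus")
  f <- ann$features
  expect_equal(f$class, c("tRNA", "PCG", "rRNA", "tRNA", "CR", "OL"))
  expect_equal(f$strand[f$name == "trnQ"], "L")
  expect_equal(f$start[f$name == "ND1"], 71L)
  expect_equal(f$anticodon[f$name == "trnF"], "GAA")
})
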