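Package: mitorearr
Title: Mitogenome Annotation Geometry, Composition, Codon Usage and
    Gene-Order Rearrangement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising annotated circular mitochondrial
    genomes and for analysing gene-order rearrangements. Reads feature
    tables (TSV or GenBank flat file) and computes annotation geometry
    (gene lengths, intergenic spacers, overlaps, start/stop codon
    classes), base composition with AT- and GC-skew per gene or feature
    class, codon usage and relative synonymous codon usage (RSCU) under
    the vertebrate mitochondrial code, and control-region motif scans.
    Extracts circular signed gene orders, compares them against the
    canonical vertebrate arrangement (translocation, inversion and
    duplication calls), infers tandem duplication-random loss (TDRL)
    scenarios by exhaustive search, and adjudicates among recombination,
    TDRL, TDNL and DRRL rearrangement models. A synthetic mitogenome
    generator emits sequence, annotation and ground truth so every
    analysis is testable without downloads; defaults emulate the
    rearranged mitogenome of the daggertooth pike conger Muraenesox
    cinereus (GenBank MT571331).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
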