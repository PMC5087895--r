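Package: lineagediv
Title: Two-Lineage Molecular Evolution Statistics for Gene Subfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Comparative molecular-evolution analysis of a gene subfamily
    split into two lineages (e.g. monocot versus dicot isoforms of an
    enzyme family). Provides identity-threshold family and subfamily
    clustering, back-translation of protein alignments to codon
    alignments, partial-deletion gap filtering, codon-position nucleotide
    composition and amino-acid composition contrasts with Student's t
    tests, relative synonymous codon usage (RSCU), within- and
    between-lineage nucleotide divergence, Nei-Gojobori dN/dS counting
    with a codon-based Z-test of selection, per-codon-site dN/dS
    categories, Tajima's D, a lineage-aware classifier of polymorphic
    amino-acid sites (fixed, overlapping and strictly dimorphic
    differences), and a seeded two-lineage sequence simulator with known
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
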