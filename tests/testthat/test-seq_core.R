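test_that("FASTA reading validates input and round-trips", {
  p <- write_temp_fasta(c(a = "ACGT"), "single.fa")
  x <- read_fasta(p, kind = "cds")
  expect_s3_class(x, "seq_set")
  expect_identical(unname(x["a"]), "ACGT")

  pd <- write_temp_fasta(c(x = "ACGT", y = "AAAA"), "dup.fa")
  writeLines(c(">x", "ACGT", ">x", "AAAA"), pd)
  expect_error(read_fasta(pd, "cds"), "duplicate.*x")

  pe <- file.path(tempdir(), "empty.fa")
  writeLines(character(0), pe)
  expect_error(read_fasta(pe, "cds"), "empty")

  set.seed(11)
  seqs <- setNames(replicate(5, random_protein(sample(10:30, 1))),
                   paste0("s", 1:5))
  out <- file.path(tempdir(), "rt.fa")
  write_fasta(seqs, out)
  back <- read_fasta(out, "protein")
  expect_identical(as.character(back), unname(seqs))
  expect_identical(names(back), names(seqs))
})

test_that("translation follows the standard code and flags stops", {
  expect_identical(unname(translate_cds("ATGGGGAAA")), "MGK")
  expect_identical(unname(translate_cds("ATGTAA")), "M")
  expect_error(translate_cds(c(bad = "ATGTAAGGG")), "codon 2")
  expect_error(translate_cds("ATGGG"), "multiple of 3")
  # ambiguity codes translate to X rather than erroring
  expect_identical(unname(translate_cds("ATGNNN")), "MX")
})

test_that("back-translation threads codons through gaps and validates", {
  aln <- protein_alignment(c(a = "M-A", b = "MKA"))
  cds <- c(a = "ATGGCT", b = "ATGAAAGCA")
  ca <- back_translate(aln, cds)
  expect_identical(unname(alignment_strings(ca)["a"]), "ATG---GCT")
  expect_identical(unname(alignment_strings(ca)["b"]), "ATGAAAGCA")

  # terminal stop on the CDS is tolerated
  ca2 <- back_translate(aln, c(a = "ATGGCTTGA", b = "ATGAAAGCA"))
  expect_identical(unname(alignment_strings(ca2)["a"]), "ATG---GCT")

  expect_error(back_translate(protein_alignment(c(a = "MV")),
                              c(a = "ATGGCG")),
               "mismatch for 'a' at residue 2")
  expect_error(back_translate(aln, cds["a"]), "missing CDS.*b")
})

test_that("back_translate . ungap . translate is the identity", {
  set.seed(42)
  for (rep in 1:5) {
    cds <- setNames(vapply(1:4, function(i) random_cds(10), character(1)),
                    paste0("s", 1:4))
    prot <- translate_cds(cds)
    aln <- protein_alignment(prot)   # trivial alignment, no gaps
    ca <- back_translate(aln, cds)
    expect_identical(alignment_strings(ca), cds)
    expect_identical(translate_cds(alignment_strings(ca)), prot)
  }
})

test_that("partial deletion removes low-coverage columns and is idempotent", {
  rows <- setNames(rep("AAAA", 10), paste0("s", 1:10))
  aln <- protein_alignment(rows)
  expect_identical(partial_deletion(aln, 0.95)$matrix, aln$matrix)

  # one gap in 10 sequences: coverage 0.9 < 0.95 threshold
  rows["s1"] <- "A-AA"
  aln <- protein_alignment(rows)
  filt <- partial_deletion(aln, 0.95)
  expect_identical(filt$columns, c(1L, 3L, 4L))
  expect_identical(attr(filt, "column_mask"), c(TRUE, FALSE, TRUE, TRUE))

  # idempotence at a fixed threshold
  refilt <- partial_deletion(filt, 0.95)
  expect_identical(refilt$matrix, filt$matrix)
  expect_identical(refilt$columns, filt$columns)

  # codon columns are atomic: any gap character gaps the codon
  ca <- codon_alignment(c(a = "ATG---", b = "ATGAAA", c = "ATGA-A",
                          d = "ATGAAA"))
  cf <- partial_deletion(ca, 0.95)
  expect_identical(cf$columns, 1L)
  expect_error(partial_deletion(ca, 1.01), "coverage")
})

test_that("partial deletion kept sets are monotone in the threshold", {
  set.seed(7)
  for (rep in 1:5) {
    m <- replicate(12, paste(sample(c(AA20, "-"), 8, TRUE,
                                    prob = c(rep(1, 20), 6)), collapse = ""))
    aln <- protein_alignment(setNames(m, paste0("s", 1:12)))
    hi <- suppressWarnings(partial_deletion(aln, 0.95))
    lo <- suppressWarnings(partial_deletion(aln, 0.50))
    expect_true(all(hi$columns %in% lo$columns))
  }
})

test_that("pairwise identity matches examples and is symmetric", {
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKL"), 100)
  expect_equal(pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV"), 90)
  expect_error(pairwise_identity("", "ACD"), "empty")
  set.seed(3)
  for (rep in 1:10) {
    a <- random_protein(sample(5:12, 1))
    b <- random_protein(sample(5:12, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a),
                 tolerance = 1e-9)
  }
})

test_that("pairwise identity agrees with the exhaustive alignment oracle", {
  set.seed(19)
  for (rep in 1:8) {
    a <- random_protein(sample(3:6, 1))
    b <- random_protein(sample(3:6, 1))
    oracle <- oracle_global_alignment(a, b)
    aln <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    expect_equal(Biostrings::score(aln), oracle$score, tolerance = 1e-6)
    got <- pairwise_identity(a, b)
    expect_true(any(abs(oracle$identities - got) < 1e-9),
                info = paste(a, b, got, "oracle:",
                             paste(round(oracle$identities, 3),
                                   collapse = "/")))
  }
})
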