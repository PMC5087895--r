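test_that("Nei-Gojobori counts match the hand-worked fixture", {
  ng0 <- nei_gojobori_pair("GGGAAA", "GGGAAA")
  expect_equal(ng0$Sd, 0); expect_equal(ng0$Nd, 0)
  expect_equal(ng0$dS, 0); expect_equal(ng0$dN, 0)

  # GGG/GGA at codon 1: synonymous Gly change; AAA has S = 1/3 because the
  # TAA single-base change is a stop and is excluded from the site count
  ng <- nei_gojobori_pair("GGGAAA", "GGAAAA")
  expect_equal(ng$S, 4 / 3, tolerance = 1e-9)
  expect_equal(ng$N, 14 / 3, tolerance = 1e-9)
  expect_equal(ng$Sd, 1); expect_equal(ng$Nd, 0)
  expect_equal(ng$pS, 0.75, tolerance = 1e-9)
  expect_equal(ng$pN, 0)
  ngjc <- nei_gojobori_pair("GGGAAA", "GGAAAA", correction = "jc")
  expect_true(is.na(ngjc$dS))
  expect_true("dS_undefined_jc" %in% ngjc$flags)
})

test_that("NG site counts satisfy S + N = 3 x codons and symmetry", {
  set.seed(17)
  for (rep in 1:10) {
    a <- random_cds(sample(5:20, 1))
    b <- random_cds(nchar(a) / 3)
    ng <- nei_gojobori_pair(a, b)
    expect_equal(ng$S + ng$N, 3 * ng$n_codons, tolerance = 1e-9)
    ng_rev <- nei_gojobori_pair(b, a)
    expect_equal(ng$Sd, ng_rev$Sd, tolerance = 1e-9)
    expect_equal(ng$Nd, ng_rev$Nd, tolerance = 1e-9)
    expect_equal(ng$S, ng_rev$S, tolerance = 1e-9)
  }
})

test_that("Sd + Nd equals raw nucleotide differences", {
  # exact for any pair: pathway averaging conserves the difference count
  set.seed(29)
  for (rep in 1:10) {
    a <- random_cds(12)
    b <- random_cds(12)
    ng <- nei_gojobori_pair(a, b)
    expect_equal(ng$Sd + ng$Nd, oracle_pair_diffs(a, b), tolerance = 1e-9)
  }
})

test_that("pairwise nucleotide distance handles gaps and JC saturation", {
  expect_equal(as.numeric(pairwise_nucleotide_distance("ACGT", "ACGT")), 0)
  expect_equal(as.numeric(pairwise_nucleotide_distance(
    "AAAAAAAAAA", "AAAAAAAACC")), 0.2)
  d <- pairwise_nucleotide_distance("AAAAA-AAAA", "AAACC-AAAA")
  expect_equal(attr(d, "sites"), 9L)
  expect_equal(as.numeric(d), 2 / 9, tolerance = 1e-12)
  expect_equal(
    as.numeric(pairwise_nucleotide_distance("AAAAAAAAAA", "AAAAAAAACC",
                                            model = "jc")),
    -0.75 * log(1 - 4 * 0.2 / 3), tolerance = 1e-12)
  expect_warning(pairwise_nucleotide_distance("AAAA", "CCCC", model = "jc"),
                 "undefined")
})

test_that("p and JC distances agree with ape::dist.dna", {
  skip_if_not_installed("ape")
  set.seed(37)
  for (rep in 1:5) {
    L <- 60
    a <- paste(sample(NT4, L, TRUE), collapse = "")
    b_chars <- strsplit(a, "")[[1]]
    flip <- sample(L, 10)
    for (i in flip) b_chars[i] <- sample(setdiff(NT4, b_chars[i]), 1)
    b <- paste(b_chars, collapse = "")
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                               b = strsplit(tolower(b), "")[[1]]))
    expect_equal(as.numeric(pairwise_nucleotide_distance(a, b)),
                 as.numeric(ape::dist.dna(bin, model = "raw")),
                 tolerance = 1e-12)
    expect_equal(as.numeric(pairwise_nucleotide_distance(a, b, model = "jc")),
                 as.numeric(ape::dist.dna(bin, model = "JC69")),
                 tolerance = 1e-9)
  }
})

test_that("group divergence averages the enumerated pairs", {
  # 2+2 alignment engineered so intra-pair p = 0.1 and inter pairs are more
  # divergent; means must equal the hand-enumerated pair averages
  base <- strrep("AAA", 10)
  w1 <- base
  w2 <- sub("^AAA", "TAA", base)                      # 1 diff of 30
  b1 <- gsub("AAAAAAAAA$", "CCCCCCCCC", base)         # 9 diffs to w1
  b2 <- sub("^AAAAAA", "GGGGGG", b1)                  # more diffs
  ids <- c("a1", "a2", "b1", "b2")
  ca <- codon_alignment(setNames(c(w1, w2, b1, b2), ids))
  part <- lineage_partition(setNames(rep(c("g1", "g2"), each = 2), ids))
  div <- group_divergence(ca, part, n_boot = 100, seed = 1)
  pdist <- function(x, y)
    as.numeric(pairwise_nucleotide_distance(x, y))
  expect_equal(div$mean[div$contrast == "within_g1"], pdist(w1, w2),
               tolerance = 1e-12)
  expect_equal(div$mean[div$contrast == "within_g2"], pdist(b1, b2),
               tolerance = 1e-12)
  expect_equal(div$mean[div$contrast == "between"],
               mean(c(pdist(w1, b1), pdist(w1, b2), pdist(w2, b1),
                      pdist(w2, b2))), tolerance = 1e-12)
  # identical groups of identical sequences -> all zero
  ca0 <- codon_alignment(setNames(rep(base, 4), ids))
  div0 <- group_divergence(ca0, part, n_boot = 100, seed = 1)
  expect_equal(div0$mean, rep(0, 3))
})

test_that("per-site dN/dS categorises engineered columns", {
  # column of identical codons -> undefined; synonymous-only column -> lt1;
  # nonsynonymous-only column -> gt1
  rows <- c(a = "AAAGGTATG", b = "AAAGGCAGG", c = "AAAGGGACG")
  # col1 invariant; col2 Gly synonymous third-position changes only;
  # col3 ATG/AGG/ACG differ at position 2 only, all nonsynonymous (M/R/T)
  ca <- codon_alignment(rows)
  psd <- per_site_dnds(ca)
  expect_identical(psd$table$category, c("undefined", "lt1", "gt1"))
  expect_equal(psd$table$ratio[2], 0)
  expect_equal(sum(psd$counts), ncol(ca$matrix))

  # 10-column toy: 2 nonsynonymous-only + 8 synonymous-only columns
  syn <- c("GGT", "GGC", "GGG")   # Gly family
  non <- c("ATG", "AGG", "ACG")   # pos-2 changes, all nonsynonymous
  rows10 <- vapply(1:3, function(i)
    paste(c(rep(syn[i], 8), rep(non[i], 2)), collapse = ""), character(1))
  ca10 <- codon_alignment(setNames(rows10, c("a", "b", "c")))
  psd10 <- per_site_dnds(ca10)
  expect_equal(unname(psd10$counts["lt1"]), 8L)
  expect_equal(unname(psd10$counts["gt1"]), 2L)
})

test_that("Z-test flags invariant alignments and rejects with strong selection", {
  ids <- paste0("s", 1:4)
  ca0 <- codon_alignment(setNames(rep(strrep("ATGGCT", 20), 4), ids))
  z0 <- codon_z_test(ca0, n_boot = 100, seed = 1)
  expect_true(is.na(z0$Z))
  expect_equal(z0$p, 1)
  expect_identical(z0$flags, "no_variation")

  sim <- simulate_lineages(n_per_lineage = c(3, 3), n_codons = 200,
                           depth_within = 0.3, depth_split = 0.3,
                           omega = 0.05, gc3 = c(0.5, 0.5),
                           n_dimorphic_sites = 0,
                           n_fixed_variable_sites = 0, seed = 101)
  z <- codon_z_test(sim$codon_aln, n_boot = 200, seed = 102)
  expect_lt(z$p, 0.05)
  expect_gt(z$mean_dS, z$mean_dN)
})

test_that("Tajima's D matches the hand-worked n=4 fixture", {
  x <- setNames(c("AAAA", "AAAA", "AAAT", "AATT"), paste0("s", 1:4))
  t <- tajimas_d(x)
  expect_identical(t$S, 2L)
  expect_equal(t$k, 7 / 6, tolerance = 1e-12)
  expect_equal(t$coefficients$a1, 11 / 6, tolerance = 1e-12)
  expect_equal(t$theta, (12 / 11) / 4, tolerance = 1e-12)
  ref <- oracle_tajima(x)
  expect_equal(t$D, ref$D, tolerance = 1e-12)
  expect_equal(round(t$D, 2), 0.59)

  # invariant input: S = 0, D undefined
  t0 <- tajimas_d(setNames(rep("ACGT", 4), paste0("s", 1:4)))
  expect_identical(t0$S, 0L)
  expect_true(is.na(t0$D))
  expect_identical(t0$flags, "no_segregating_sites")
  expect_error(tajimas_d(setNames(rep("ACGT", 3), paste0("s", 1:3))),
               "at least 4")
})

test_that("Tajima's D sign tracks pi - theta and complete deletion drops gaps", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    L <- sample(20:50, 1)
    m <- matrix(sample(c(NT4, "-"), n * L, TRUE, prob = c(4, 4, 4, 4, 1)),
                n, L, dimnames = list(paste0("s", 1:n), NULL))
    rows <- apply(m, 1, paste, collapse = "")
    res <- try(tajimas_d(rows), silent = TRUE)
    if (inherits(res, "try-error") || res$S == 0) next
    ref <- oracle_tajima(rows)
    expect_equal(res$D, ref$D, tolerance = 1e-12)
    expect_equal(res$pi, ref$pi, tolerance = 1e-12)
    expect_equal(res$theta, ref$theta, tolerance = 1e-12)
    expect_identical(sign(res$D), sign(res$pi - res$theta))
  }
})
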