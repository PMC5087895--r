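aln4 <- function(rows) protein_alignment(setNames(rows, paste0("s", seq_along(rows))))

test_that("parsimony-informative rule: two states, each at least twice", {
  aln <- aln4(c("AA-AY", "AAVAY", "AAVCY", "VACAY", "VA-DY"))
  # col1 A,A,A,V,V -> informative; col2 invariant; col3 -,V,V,C,- not
  # (only one state appears twice); col4 A,A,C,A,D not; col5 invariant
  expect_identical(parsimony_informative_sites(aln), 1L)
  expect_error(parsimony_informative_sites(aln4(c("AA", "AA", "AA"))),
               "at least 4")
  # gaps are ignored as states: A,A,-,V,V informative
  expect_identical(parsimony_informative_sites(aln4(c("A", "A", "-", "V", "V"))),
                   1L)
})

test_that("informative sites agree with the per-column counting oracle", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(4:10, 1)
    L <- sample(10:50, 1)
    m <- matrix(sample(c("A", "C", "G", "T", "-", "N"), n * L, TRUE,
                       prob = c(rep(4, 4), 2, 1)), n, L)
    rownames(m) <- paste0("s", 1:n)
    expect_identical(parsimony_informative_sites(m, alphabet = NT4),
                     oracle_informative(m, NT4))
  }
})

test_that("lineage site classification reproduces the reported patterns", {
  # 4 dicots fixed vs 4 monocots; columns built to hit every category
  dic <- c("AFYIK", "AFYIK", "AFYIK", "AFYIK")
  mon <- c("TFFIK", "GYFVK", "SFFVK", "TYFIK")
  aln <- protein_alignment(setNames(c(dic, mon),
                                    c(paste0("d", 1:4), paste0("m", 1:4))))
  part <- lineage_partition(setNames(rep(c("dicot", "monocot"), each = 4),
                                     rownames(aln$matrix)))
  cls <- classify_lineage_sites(aln, part, sites = "all")
  # col1: dicot {A} vs monocot {T,G,S} disjoint, one side fixed
  expect_identical(cls$category[1], "fixed_in_dicot_variable_in_monocot")
  expect_identical(cls$residues_monocot[1], "T, G, S")
  # col2: dicot {F} vs monocot {F,Y} -> overlapping
  expect_identical(cls$category[2], "overlapping")
  # col3: dicot {Y} vs monocot {F} -> strictly dimorphic
  expect_identical(cls$category[3], "strictly_dimorphic")
  # col4: overlapping (I vs I,V); col5: invariant
  expect_identical(cls$category[5], "invariant")

  # swapping lineage labels mirrors fixed/variable categories
  part_sw <- lineage_partition(setNames(rep(c("monocot", "dicot"), each = 4),
                                        rownames(aln$matrix)))
  cls_sw <- classify_lineage_sites(aln, part_sw, sites = "all")
  expect_identical(cls_sw$category[1], "fixed_in_monocot_variable_in_dicot")
  expect_identical(cls_sw$category[3], "strictly_dimorphic")

  # row order does not matter
  perm <- sample(rownames(aln$matrix))
  aln_p <- protein_alignment(alignment_strings(aln)[perm])
  cls_p <- classify_lineage_sites(aln_p, part, sites = "all")
  expect_identical(cls_p$category, cls$category)

  expect_error(classify_lineage_sites(aln, part, columns = 99), "out of range")
})

test_that("residue-set formatting orders by frequency then alphabet", {
  aln <- protein_alignment(setNames(c("G", "G", "A", "T", "T", "S"),
                                    paste0("x", 1:6)))
  part <- lineage_partition(setNames(c(rep("dicot", 2), rep("monocot", 4)),
                                     paste0("x", 1:6)))
  cls <- classify_lineage_sites(aln, part, sites = "all")
  expect_identical(cls$residues_monocot[1], "T, A, S")
})

test_that("column to residue numbering skips gaps", {
  aln <- protein_alignment(c(a = "M-AC", b = "MKAC"))
  expect_identical(column_to_residue_number(aln, "a", 3), 2L)
  expect_identical(column_to_residue_number(aln, "b", 3), 3L)
  expect_identical(column_to_residue_number(aln, "a", 1), 1L)
  expect_error(column_to_residue_number(aln, "a", 2), "gap")
  # dimorphic-site style report: same column, different isoform numbering
  aln2 <- protein_alignment(c(At = "MA-Y", Bd = "M-AF"))
  expect_identical(column_to_residue_number(aln2, "At", 4), 3L)
  expect_identical(column_to_residue_number(aln2, "Bd", 4), 3L)
})

test_that("partition parsing validates two-lineage structure", {
  path <- file.path(tempdir(), "part.tsv")
  writeLines(c("# comment", "a\tdicot", "b\tdicot", "c\tmonocot",
               "d\tmonocot"), path)
  p <- read_partition(path)
  expect_identical(attr(p, "lineages"), c("dicot", "monocot"))
  expect_error(lineage_partition(setNames(c("x", "y", "z"),
                                          c("a", "b", "c"))),
               "exactly two")
  expect_warning(lineage_partition(setNames(c("x", "x", "y"),
                                            c("a", "b", "c"))),
                 "fewer than 2")
})

test_that("column_to_residue_number is 1 at every row's first residue", {
  set.seed(4)
  for (rep in 1:5) {
    rows <- vapply(1:4, function(i) {
      chars <- sample(c(AA20, "-"), 12, TRUE)
      if (all(chars == "-")) chars[1] <- "M"
      paste(chars, collapse = "")
    }, character(1))
    aln <- protein_alignment(setNames(rows, paste0("s", 1:4)))
    for (id in rownames(aln$matrix)) {
      first <- which(aln$matrix[id, ] != "-")[1]
      expect_identical(column_to_residue_number(aln, id, first), 1L)
    }
  }
})
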