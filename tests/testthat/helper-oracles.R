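# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately re-derive every
# quantity from first principles and share no code with R/.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
NT4 <- c("T", "C", "A", "G")

random_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# a random sense-codon CDS under the standard code
random_cds <- function(n_codons) {
  tab <- Biostrings::getGeneticCode("1")
  sense <- names(tab)[tab != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# ---- exhaustive global-alignment oracle (affine gaps) ---------------------

# enumerate every global alignment of two character vectors as move strings
# (M = aligned column, P = gap in subject, S = gap in pattern)
enumerate_alignments <- function(na, nb) {
  rec <- function(i, j) {
    if (i == na && j == nb) return(list(character(0)))
    out <- list()
    if (i < na && j < nb)
      out <- c(out, lapply(rec(i + 1, j + 1), function(m) c("M", m)))
    if (i < na)
      out <- c(out, lapply(rec(i + 1, j), function(m) c("P", m)))
    if (j < nb)
      out <- c(out, lapply(rec(i, j + 1), function(m) c("S", m)))
    out
  }
  rec(0L, 0L)
}

score_alignment <- function(moves, av, bv, submat, gap_open, gap_extend) {
  score <- 0; i <- 0L; j <- 0L; prev <- "M"
  for (m in moves) {
    if (m == "M") {
      i <- i + 1L; j <- j + 1L
      score <- score + submat[av[i], bv[j]]
    } else {
      if (m != prev) score <- score - gap_open
      score <- score - gap_extend
      if (m == "P") i <- i + 1L else j <- j + 1L
    }
    prev <- m
  }
  score
}

identity_of_alignment <- function(moves, av, bv) {
  # matches / columns, excluding terminal gap columns
  n <- length(moves)
  first <- match("M", moves)
  last <- n + 1L - match("M", rev(moves))
  keep <- seq(first, last)
  i <- 0L; j <- 0L; matches <- 0L
  for (k in seq_len(n)) {
    m <- moves[k]
    if (m == "M") {
      i <- i + 1L; j <- j + 1L
      if (av[i] == bv[j] && av[i] != "X") matches <- matches + 1L
    } else if (m == "P") i <- i + 1L else j <- j + 1L
  }
  100 * matches / length(keep)
}

# returns best affine-gap score and the identities of all co-optimal
# alignments under the package's identity definition
oracle_global_alignment <- function(a, b, gap_open = 10, gap_extend = 0.5) {
  submat <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  alns <- enumerate_alignments(length(av), length(bv))
  scores <- vapply(alns, score_alignment, numeric(1), av = av, bv = bv,
                   submat = submat, gap_open = gap_open,
                   gap_extend = gap_extend)
  best <- max(scores)
  opt <- alns[abs(scores - best) < 1e-9]
  list(score = best,
       identities = vapply(opt, identity_of_alignment, numeric(1),
                           av = av, bv = bv))
}

get_blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

# ---- parsimony-informative oracle -----------------------------------------

oracle_informative <- function(m, alphabet) {
  out <- integer(0)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col %in% alphabet]
    n_states_twice <- 0L
    for (st in unique(col)) {
      cnt <- 0L
      for (v in col) if (v == st) cnt <- cnt + 1L
      if (cnt >= 2L) n_states_twice <- n_states_twice + 1L
    }
    if (n_states_twice >= 2L) out <- c(out, j)
  }
  out
}

# ---- Tajima's D oracle ------------------------------------------------------

oracle_tajima <- function(rows) {
  m <- do.call(rbind, strsplit(rows, ""))
  keep <- apply(m, 2, function(col) all(col %in% NT4))
  m <- m[, keep, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  S <- 0L
  for (j in seq_len(L)) if (length(unique(m[, j])) > 1L) S <- S + 1L
  total <- 0; npairs <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    total <- total + sum(m[i, ] != m[j, ]); npairs <- npairs + 1
  }
  kbar <- total / npairs
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  D <- if (S == 0) NA_real_ else
    (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, kbar = kbar, pi = kbar / L, theta = S / (a1 * L), D = D,
       L = L, a1 = a1)
}

# ---- misc ------------------------------------------------------------------

# raw nucleotide differences between two codon strings over columns where
# both codons are sense codons
oracle_pair_diffs <- function(a, b) {
  tab <- Biostrings::getGeneticCode("1")
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  total <- 0L
  for (k in seq_along(ca)) {
    ok <- ca[k] %in% names(tab) && cb[k] %in% names(tab) &&
      tab[[ca[k]]] != "*" && tab[[cb[k]]] != "*"
    if (!ok) next
    total <- total + sum(strsplit(ca[k], "")[[1]] != strsplit(cb[k], "")[[1]])
  }
  total
}

# small helper: write a fasta fixture into tempdir
write_temp_fasta <- function(seqs, name = "fix.fa") {
  path <- file.path(tempdir(), name)
  con <- file(path, "wt")
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  close(con)
  path
}
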