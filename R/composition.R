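#' Pooled-variance two-sample Student's t test
#'
#' Thin wrapper around [stats::t.test()] with `var.equal = TRUE` (Welch's
#' correction available behind `welch = TRUE`) plus explicit handling of
#' the degenerate zero-variance cases that arise on invariant alignment
#' cells: equal means give `t = 0, p = 1`; unequal means are flagged with
#' an infinite t and `p = 0`.
#'
#' @param x,y Numeric vectors, each of length at least 2.
#' @param welch Use Welch's unequal-variance t instead of the pooled t.
#' @return List with `t`, `p`, `df`, `degenerate`.
#' @export
students_t <- function(x, y, welch = FALSE) {
  if (length(x) < 2L || length(y) < 2L)
    stop("each group needs at least 2 values")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, p = 1, df = length(x) + length(y) - 2L,
                  degenerate = TRUE))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0,
                df = length(x) + length(y) - 2L, degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), degenerate = FALSE)
}

composition_stats <- function(per_seq, partition, cells) {
  lin <- attr(partition, "lineages")
  rows <- lapply(seq_along(cells), function(k) {
    a <- per_seq[partition[rownames(per_seq)] == lin[1], k]
    b <- per_seq[partition[rownames(per_seq)] == lin[2], k]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    tt <- if (length(a) < 2L || length(b) < 2L)
      list(t = NA_real_, p = NA_real_) else students_t(a, b)
    data.frame(cell = cells[k],
               mean_A = mean(a), se_A = sd(a) / sqrt(length(a)),
               sd_A = sd(a),
               mean_B = mean(b), se_B = sd(b) / sqrt(length(b)),
               sd_B = sd(b),
               t = tt$t, p = tt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  lab <- c(A = lin[1], B = lin[2])
  names(out) <- sub("_A$", paste0("_", lab["A"]), names(out))
  names(out) <- sub("_B$", paste0("_", lab["B"]), names(out))
  attr(out, "lineages") <- lin
  out
}

#' Nucleotide composition by codon position, contrasted between lineages
#'
#' For each sequence, base frequencies (percent over T/C/A/G) are computed
#' separately at codon positions 1, 2 and 3, restricted to the retained
#' site filter (default: parsimony-informative nucleotide columns of the
#' codon alignment). Gapped and ambiguous cells are excluded from both
#' numerator and denominator, so each position's four frequencies sum to
#' 100 per sequence. Group means are contrasted per cell with the pooled
#' Student's t test (SE and SD both reported).
#'
#' @param codon_aln A [codon_alignment()].
#' @param partition A [lineage_partition()].
#' @param site_filter `"informative"` (default) or `"all"`.
#' @return data.frame of class `composition_table` with one row per cell
#'   (`T-1` ... `G-3`), lineage means/SE/SD, `t` and `p`; attribute
#'   `per_sequence` holds the per-sequence percentage matrix.
#' @export
codon_position_composition <- function(codon_aln, partition,
                                       site_filter = c("informative", "all")) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  site_filter <- match.arg(site_filter)
  check_partition_covers(partition, rownames(codon_aln$matrix))
  nt <- as_nucleotide_matrix(codon_aln)
  keep <- if (site_filter == "informative")
    parsimony_informative_sites(nt$matrix, alphabet = NUCLEOTIDES)
  else seq_len(ncol(nt$matrix))
  if (length(keep) == 0L)
    stop("site filter retained zero nucleotide columns")
  m <- nt$matrix[, keep, drop = FALSE]
  pos <- nt$position[keep]
  cells <- paste0(rep(NUCLEOTIDES, 3), "-", rep(1:3, each = 4))
  per_seq <- matrix(NA_real_, nrow(m), 12,
                    dimnames = list(rownames(m), cells))
  for (i in seq_len(nrow(m))) {
    for (p in 1:3) {
      bases <- states_of(m[i, pos == p], NUCLEOTIDES)
      if (length(bases) == 0L) next
      counts <- table(factor(bases, levels = NUCLEOTIDES))
      per_seq[i, (p - 1L) * 4L + 1:4] <- 100 * as.numeric(counts) /
        length(bases)
    }
  }
  out <- composition_stats(per_seq, partition, cells)
  out$base <- rep(NUCLEOTIDES, 3)
  out$position <- rep(1:3, each = 4)
  attr(out, "per_sequence") <- per_seq
  attr(out, "n_sites") <- length(keep)
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Amino-acid composition contrasted between lineages
#'
#' Per-sequence amino-acid frequencies (percent over the 20 residues,
#' gaps/ambiguities excluded) restricted to a site filter (default: the
#' parsimony-informative columns of the protein alignment), with per-residue
#' pooled t tests between the two lineages.
#'
#' @param alignment A [protein_alignment()].
#' @param partition A [lineage_partition()].
#' @param site_filter `"informative"` (default) or `"all"`.
#' @return data.frame of class `composition_table`, one row per amino acid.
#' @export
amino_acid_composition <- function(alignment, partition,
                                   site_filter = c("informative", "all")) {
  stopifnot(inherits(alignment, "protein_alignment"))
  site_filter <- match.arg(site_filter)
  check_partition_covers(partition, rownames(alignment$matrix))
  keep <- if (site_filter == "informative")
    parsimony_informative_sites(alignment)
  else seq_len(ncol(alignment$matrix))
  if (length(keep) == 0L)
    stop("site filter retained zero columns")
  m <- alignment$matrix[, keep, drop = FALSE]
  per_seq <- matrix(NA_real_, nrow(m), 20,
                    dimnames = list(rownames(m), AMINO_ACIDS))
  for (i in seq_len(nrow(m))) {
    res <- states_of(m[i, ], AMINO_ACIDS)
    if (length(res) == 0L) next
    counts <- table(factor(res, levels = AMINO_ACIDS))
    per_seq[i, ] <- 100 * as.numeric(counts) / length(res)
  }
  out <- composition_stats(per_seq, partition, AMINO_ACIDS)
  names(out)[names(out) == "cell"] <- "amino_acid"
  attr(out, "per_sequence") <- per_seq
  attr(out, "n_sites") <- length(keep)
  class(out) <- c("composition_table", "data.frame")
  out
}

#' Relative synonymous codon usage
#'
#' `RSCU(c) = count(c) / mean(counts of c's synonymous codons)` over the
#' pooled codon counts of a CDS set. Stop codons and single-codon families
#' (Met and Trp under the standard code) are excluded. A synonymous family
#' with zero total count yields `NA` RSCU values flagged in the `defined`
#' column rather than 0/0.
#'
#' @param cds Named character vector of CDS sequences (codons containing
#'   non-ACGT characters are skipped).
#' @param code A [genetic_code()].
#' @return data.frame of class `rscu_table` with columns `codon`,
#'   `amino_acid`, `count`, `rscu`, `defined`.
#' @export
rscu <- function(cds, code = genetic_code()) {
  tab <- code$table
  codons <- unlist(lapply(as.character(cds), split_codons),
                   use.names = FALSE)
  codons <- codons[codons %in% names(tab)]
  counts <- table(factor(codons, levels = names(tab)))
  fam <- split(names(tab), tab)
  fam <- fam[names(fam) != "*"]
  fam <- fam[vapply(fam, length, integer(1)) > 1L]
  rows <- lapply(names(fam), function(aa) {
    cs <- sort(fam[[aa]])
    cnt <- as.numeric(counts[cs])
    defined <- sum(cnt) > 0
    data.frame(codon = cs, amino_acid = aa, count = cnt,
               rscu = if (defined) cnt / mean(cnt) else NA_real_,
               defined = defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$amino_acid, out$codon), ]
  rownames(out) <- NULL
  class(out) <- c("rscu_table", "data.frame")
  out
}
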