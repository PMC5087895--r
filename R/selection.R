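#' Pairwise nucleotide distance between two gapped rows
#'
#' Pairwise deletion: only columns where both rows carry an unambiguous
#' base (A/C/G/T) are compared. `model = "p"` returns the proportion of
#' differing sites; `model = "jc"` applies the Jukes-Cantor correction,
#' which is undefined (returned as `NA` with a warning) when `p >= 0.75`.
#'
#' @param a,b Equal-length nucleotide strings, `-` gaps allowed.
#' @param model `"p"` (default) or `"jc"`.
#' @return Numeric distance with attribute `sites` (columns compared).
#' @export
pairwise_nucleotide_distance <- function(a, b, model = c("p", "jc")) {
  model <- match.arg(model)
  av <- strsplit(toupper(as.character(a)), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(as.character(b)), "", fixed = TRUE)[[1]]
  if (length(av) != length(bv)) stop("rows have different lengths")
  ok <- av %in% NUCLEOTIDES & bv %in% NUCLEOTIDES
  if (!any(ok)) stop("no shared non-gap column")
  p <- sum(av[ok] != bv[ok]) / sum(ok)
  d <- if (model == "jc") {
    jc <- jukes_cantor(p)
    if (is.na(jc)) warning("Jukes-Cantor distance undefined at p = ",
                           signif(p, 4))
    jc
  } else p
  structure(d, sites = sum(ok))
}

all_pairs <- function(ids) {
  if (length(ids) < 2L) return(matrix(character(0), ncol = 2))
  t(combn(ids, 2L))
}

# Per-pair mismatch/comparable indicator matrices over nucleotide columns.
pair_mismatch_profiles <- function(nt, pairs) {
  np <- nrow(pairs)
  L <- ncol(nt)
  mism <- matrix(0L, np, L)
  comp <- matrix(0L, np, L)
  valid <- matrix(nt %in% NUCLEOTIDES, nrow = nrow(nt))
  for (k in seq_len(np)) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ok <- valid[i, ] & valid[j, ]
    comp[k, ] <- as.integer(ok)
    mism[k, ok] <- as.integer(nt[i, ok] != nt[j, ok])
  }
  list(mismatch = mism, comparable = comp)
}

#' Within- and between-lineage nucleotide divergence
#'
#' Mean pairwise nucleotide distance (pairwise deletion) over all
#' intra-group pairs of each lineage and over all inter-group pairs, with
#' standard errors from a seeded bootstrap over nucleotide sites.
#'
#' @param codon_aln A [codon_alignment()] (distances are computed on its
#'   nucleotide expansion).
#' @param partition A [lineage_partition()].
#' @param model `"p"` or `"jc"`.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Optional RNG seed.
#' @return data.frame of class `group_divergence` with one row per
#'   contrast (`within_<A>`, `within_<B>`, `between`), columns `mean`,
#'   `se`, `n_pairs`; attributes `model`, `n_boot`.
#' @export
group_divergence <- function(codon_aln, partition, model = c("p", "jc"),
                             n_boot = 1000L, seed = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(codon_aln, "codon_alignment"))
  check_partition_covers(partition, rownames(codon_aln$matrix))
  if (!is.null(seed)) set.seed(seed)
  nt <- as_nucleotide_matrix(codon_aln)$matrix
  ids <- rownames(nt)
  lin <- attr(partition, "lineages")
  idsA <- partition_ids(partition, lin[1], ids)
  idsB <- partition_ids(partition, lin[2], ids)
  if (length(idsA) < 2L || length(idsB) < 2L)
    stop("each lineage needs at least 2 sequences")
  idx <- setNames(seq_along(ids), ids)
  pairs <- rbind(
    cbind(matrix(idx[all_pairs(idsA)], ncol = 2), 1L),
    cbind(matrix(idx[all_pairs(idsB)], ncol = 2), 2L),
    cbind(as.matrix(expand.grid(idx[idsA], idx[idsB])), 3L))
  prof <- pair_mismatch_profiles(nt, pairs[, 1:2, drop = FALSE])
  group <- pairs[, 3]
  dist_fun <- function(cols) {
    m <- rowSums(prof$mismatch[, cols, drop = FALSE])
    n <- rowSums(prof$comparable[, cols, drop = FALSE])
    p <- ifelse(n > 0, m / n, NA_real_)
    if (model == "jc") jukes_cantor(p) else p
  }
  d_obs <- dist_fun(seq_len(ncol(nt)))
  means <- tapply(d_obs, group, mean, na.rm = TRUE)
  boot <- matrix(NA_real_, n_boot, 3)
  for (r in seq_len(n_boot)) {
    cols <- sample.int(ncol(nt), replace = TRUE)
    boot[r, ] <- tapply(dist_fun(cols), group, mean, na.rm = TRUE)
  }
  out <- data.frame(
    contrast = c(paste0("within_", lin[1]), paste0("within_", lin[2]),
                 "between"),
    mean = as.numeric(means[c("1", "2", "3")]),
    se = apply(boot, 2, sd, na.rm = TRUE),
    n_pairs = as.integer(table(factor(group, levels = 1:3))),
    stringsAsFactors = FALSE)
  attr(out, "model") <- model
  attr(out, "n_boot") <- n_boot
  class(out) <- c("group_divergence", "data.frame")
  out
}

# per-pair per-column NG arrays for an alignment
ng_profiles <- function(codon_aln, pairs, tables) {
  idx <- codon_index_matrix(codon_aln, tables)
  np <- nrow(pairs)
  L <- ncol(idx)
  SDm <- matrix(NA_real_, np, L); NDm <- SDm; Sm <- SDm
  for (k in seq_len(np)) {
    prof <- ng_pair_profile(idx[pairs[k, 1], ], idx[pairs[k, 2], ], tables)
    SDm[k, ] <- prof$sd; NDm[k, ] <- prof$nd; Sm[k, ] <- prof$s
  }
  list(SD = SDm, ND = NDm, S = Sm)
}

# mean dS and dN across pairs for a column subset
ng_means <- function(prof, cols, correction) {
  Sd <- rowSums(prof$SD[, cols, drop = FALSE], na.rm = TRUE)
  Nd <- rowSums(prof$ND[, cols, drop = FALSE], na.rm = TRUE)
  S <- rowSums(prof$S[, cols, drop = FALSE], na.rm = TRUE)
  ncod <- rowSums(!is.na(prof$S[, cols, drop = FALSE]))
  N <- 3 * ncod - S
  pS <- ifelse(S > 0, Sd / S, 0)
  pN <- ifelse(N > 0, Nd / N, 0)
  if (correction == "jc") {
    dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
  } else {
    dS <- pS; dN <- pN
  }
  c(dS = mean(dS, na.rm = TRUE), dN = mean(dN, na.rm = TRUE))
}

#' Codon-based Z-test of selection
#'
#' Tests strict neutrality (`dN = dS`) against purifying (`dS > dN`),
#' positive (`dN > dS`) or two-sided alternatives using Nei-Gojobori
#' counts averaged over sequence pairs, with the variance of `dS - dN`
#' estimated by a seeded bootstrap over codon sites:
#' `Z = (mean dS - mean dN) / sqrt(Var(dS) + Var(dN))`.
#'
#' @param codon_aln A [codon_alignment()].
#' @param partition Optional [lineage_partition()]; with `scope` it
#'   restricts which sequence pairs enter the average.
#' @param scope `"all"` pairs (default), `"within"` lineage pairs only, or
#'   `"between"` lineage pairs only (ignored without a partition).
#' @param alternative `"purifying"`, `"positive"`, or `"neutral"`
#'   (two-sided).
#' @param n_boot Bootstrap replicates (>= 100; default 1000).
#' @param seed Optional RNG seed.
#' @param correction `"none"` or `"jc"`.
#' @param code A [genetic_code()].
#' @return List of class `codon_z_test`: `Z`, `p`, `mean_dS`, `mean_dN`,
#'   `var_dS`, `var_dN`, `n_pairs`, `n_boot`, `alternative`, `flags`.
#'   An alignment with no variation is flagged and returns `Z = NA`,
#'   `p = 1`.
#' @export
codon_z_test <- function(codon_aln, partition = NULL,
                         scope = c("all", "within", "between"),
                         alternative = c("purifying", "positive", "neutral"),
                         n_boot = 1000L, seed = NULL,
                         correction = c("none", "jc"),
                         code = genetic_code()) {
  scope <- match.arg(scope)
  alternative <- match.arg(alternative)
  correction <- match.arg(correction)
  stopifnot(inherits(codon_aln, "codon_alignment"))
  if (n_boot < 100L) stop("n_boot must be at least 100")
  if (nrow(codon_aln$matrix) < 2L) stop("need at least 2 sequences")
  if (!is.null(seed)) set.seed(seed)
  tables <- ng_tables(code)
  ids <- rownames(codon_aln$matrix)
  idx <- setNames(seq_along(ids), ids)
  pr <- all_pairs(ids)
  if (!is.null(partition) && scope != "all") {
    check_partition_covers(partition, ids)
    same <- partition[pr[, 1]] == partition[pr[, 2]]
    pr <- pr[if (scope == "within") same else !same, , drop = FALSE]
  }
  pairs <- matrix(idx[pr], ncol = 2)
  prof <- ng_profiles(codon_aln, pairs, tables)
  if (sum(prof$SD, na.rm = TRUE) + sum(prof$ND, na.rm = TRUE) == 0) {
    return(structure(list(Z = NA_real_, p = 1, mean_dS = 0, mean_dN = 0,
                          var_dS = 0, var_dN = 0, n_pairs = nrow(pairs),
                          n_boot = n_boot, alternative = alternative,
                          flags = "no_variation"), class = "codon_z_test"))
  }
  L <- ncol(codon_aln$matrix)
  obs <- ng_means(prof, seq_len(L), correction)
  boot <- matrix(NA_real_, n_boot, 2)
  for (r in seq_len(n_boot))
    boot[r, ] <- ng_means(prof, sample.int(L, replace = TRUE), correction)
  v <- apply(boot, 2, var, na.rm = TRUE)
  Z <- (obs["dS"] - obs["dN"]) / sqrt(sum(v))
  p <- switch(alternative,
              purifying = pnorm(Z, lower.tail = FALSE),
              positive = pnorm(Z),
              neutral = 2 * pnorm(-abs(Z)))
  structure(list(Z = unname(Z), p = unname(p),
                 mean_dS = unname(obs["dS"]), mean_dN = unname(obs["dN"]),
                 var_dS = v[1], var_dN = v[2],
                 n_pairs = nrow(pairs), n_boot = n_boot,
                 alternative = alternative, flags = character(0)),
            class = "codon_z_test")
}

#' @export
print.codon_z_test <- function(x, ...) {
  cat(sprintf(
    "Codon Z-test (%s): Z = %.3f, p = %.4g (mean dS %.4f, mean dN %.4f, %d pairs)\n",
    x$alternative, x$Z, x$p, x$mean_dS, x$mean_dN, x$n_pairs))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Per-codon-site dN/dS categories
#'
#' For every codon column, Nei-Gojobori differences and sites are averaged
#' over all sequence pairs (pairwise deletion), giving a per-site ratio
#' `(Nd/N) / (Sd/S)`. Columns are categorised as `gt1` (ratio above 1,
#' including nonsynonymous-only columns where the ratio is infinite),
#' `lt1`, `eq1` (ratio exactly 1) or `undefined` (no differences or no
#' comparable pair).
#'
#' @param codon_aln A [codon_alignment()] with at least 3 sequences.
#' @param code A [genetic_code()].
#' @return List of class `per_site_dnds`: `table` (data.frame column, Sd,
#'   Nd, S, N, ratio, category) and `counts` (named category counts; the
#'   counts always sum to the number of codon columns).
#' @export
per_site_dnds <- function(codon_aln, code = genetic_code()) {
  stopifnot(inherits(codon_aln, "codon_alignment"))
  if (nrow(codon_aln$matrix) < 3L) stop("need at least 3 sequences")
  tables <- ng_tables(code)
  ids <- rownames(codon_aln$matrix)
  idx <- setNames(seq_along(ids), ids)
  pairs <- matrix(idx[all_pairs(ids)], ncol = 2)
  prof <- ng_profiles(codon_aln, pairs, tables)
  L <- ncol(codon_aln$matrix)
  rows <- lapply(seq_len(L), function(j) {
    ok <- !is.na(prof$S[, j])
    if (!any(ok))
      return(data.frame(column = codon_aln$columns[j], Sd = NA_real_,
                        Nd = NA_real_, S = NA_real_, N = NA_real_,
                        ratio = NA_real_, category = "undefined",
                        stringsAsFactors = FALSE))
    Sd <- mean(prof$SD[ok, j]); Nd <- mean(prof$ND[ok, j])
    S <- mean(prof$S[ok, j]); N <- 3 - S
    ratio <- if (Sd + Nd == 0) NA_real_
             else if (Sd == 0) Inf
             else (Nd / N) / (Sd / S)
    category <- if (is.na(ratio)) "undefined"
                else if (ratio > 1) "gt1"
                else if (ratio < 1) "lt1"
                else "eq1"
    data.frame(column = codon_aln$columns[j], Sd = Sd, Nd = Nd, S = S,
               N = N, ratio = ratio, category = category,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts <- table(factor(tab$category,
                         levels = c("gt1", "lt1", "eq1", "undefined")))
  structure(list(table = tab, counts = counts), class = "per_site_dnds")
}

#' @export
print.per_site_dnds <- function(x, ...) {
  cat("Per-site dN/dS over", nrow(x$table), "codon columns:\n")
  print(x$counts)
  invisible(x)
}
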