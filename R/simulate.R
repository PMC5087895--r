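# Seeded two-lineage codon-alignment simulator with known ground truth.
#
# The model is deliberately simple: a shared ancestral CDS is drawn
# codon-wise (third-position base biased toward the midpoint of the two
# lineage GC3 targets), two lineage ancestors evolve from it along a split
# branch, and each tip evolves independently from its lineage ancestor
# (a star phylogeny within each lineage). Substitution events propose one
# of the nine single-base codon neighbours; stop codons are never
# accepted, nonsynonymous proposals are down-weighted by omega, and
# synonymous third-position choices are weighted toward the lineage GC3
# target. Lineage-fixed amino-acid sites are overwritten last. No indels
# are simulated, so the codon "alignment" is the sequence set itself.

.sim_cache <- new.env(parent = emptyenv())

codon_neighbours <- function(code) {
  key <- as.character(code$id)
  cached <- get0(key, envir = .sim_cache)
  if (!is.null(cached)) return(cached)
  tab <- code$table
  sense <- names(tab)[tab != "*"]
  nb <- lapply(sense, function(codon) {
    chars <- strsplit(codon, "", fixed = TRUE)[[1]]
    targets <- character(0); syn <- logical(0)
    pos3 <- logical(0); gc <- logical(0)
    for (pos in 1:3) {
      for (b in setdiff(NUCLEOTIDES, chars[pos])) {
        x <- chars; x[pos] <- b
        cand <- paste(x, collapse = "")
        if (tab[[cand]] == "*") next
        targets <- c(targets, cand)
        syn <- c(syn, tab[[cand]] == tab[[codon]])
        pos3 <- c(pos3, pos == 3L)
        gc <- c(gc, b %in% c("G", "C"))
      }
    }
    list(targets = targets, syn = syn, pos3 = pos3, gc = gc)
  })
  names(nb) <- sense
  out <- list(nb = nb, sense = sense, tab = tab)
  assign(key, out, envir = .sim_cache)
  out
}

# Per-codon substitution weights for one branch: synonymous changes have
# weight 1 (third-position choices rescaled toward the lineage GC3
# target), nonsynonymous changes weight omega, stop codons weight 0.
branch_weights <- function(nbinfo, omega, gc3) {
  lapply(nbinfo$nb, function(nbj) {
    ifelse(nbj$syn, 1, omega) *
      ifelse(nbj$pos3, ifelse(nbj$gc, 2 * gc3, 2 * (1 - gc3)), 1)
  })
}

# Gillespie-style branch evolution: the expected number of substitutions
# per codon is depth; each event picks a codon proportionally to its total
# substitution weight and a target codon proportionally to the per-change
# weights, i.e. the embedded jump chain of the continuous-time codon model
# with the rates above. Rate-proportional timing is what makes the
# third-position stationary frequencies match the GC3 target.
evolve_codons <- function(cod, depth, omega, gc3, nbinfo) {
  n_events <- rpois(1L, depth * length(cod))
  if (n_events == 0L) return(cod)
  wlist <- branch_weights(nbinfo, omega, gc3)
  wtot <- vapply(wlist, sum, numeric(1))
  W <- wtot[cod]
  for (e in seq_len(n_events)) {
    if (all(W <= 0)) break
    j <- sample.int(length(cod), 1L, prob = W)
    w <- wlist[[cod[j]]]
    pick <- sample.int(length(w), 1L, prob = w)
    cod[j] <- nbinfo$nb[[cod[j]]]$targets[pick]
    W[j] <- wtot[cod[j]]
  }
  cod
}

codon_for <- function(aa, gc3, tab) {
  cands <- names(tab)[tab == aa]
  base3 <- substr(cands, 3, 3)
  w <- ifelse(base3 %in% c("G", "C"), gc3, 1 - gc3)
  if (sum(w) <= 0) w <- rep(1, length(cands))
  cands[sample.int(length(cands), 1L, prob = w)]
}

#' Simulate a two-lineage codon alignment with known ground truth
#'
#' Generates gap-free CDS sets for two lineages descending from a common
#' ancestor, under purifying (or neutral) selection with lineage-specific
#' GC3 bias, and injects a configurable number of lineage-fixed amino-acid
#' sites: strictly dimorphic columns (each lineage fixed for a different
#' residue) and fixed-in-one / variable-in-the-other columns whose variable
#' lineage carries 2-4 residues disjoint from the fixed one. The same seed
#' reproduces the output exactly.
#'
#' Defaults emulate the structure of a dicot/monocot enzyme subfamily
#' comparison: 8 + 15 sequences of 423 codons under strong purifying
#' selection (omega 0.1), AT-rich third positions in the first lineage and
#' GC-rich in the second, one strictly dimorphic site and three sites fixed
#' in the first lineage but variable in the second.
#'
#' @param n_per_lineage Integer vector of two tip counts (default `c(8, 15)`).
#' @param n_codons Number of codons (default 423).
#' @param depth_within Expected accepted substitutions per codon from each
#'   lineage ancestor to a tip (recycled to length 2).
#' @param depth_split Expected accepted substitutions per codon from the
#'   root to each lineage ancestor.
#' @param omega Target dN/dS: acceptance weight of nonsynonymous proposals.
#' @param gc3 Length-2 vector of lineage GC3 targets in (0, 1).
#' @param n_dimorphic_sites Injected strictly-dimorphic columns.
#' @param n_fixed_variable_sites Injected fixed/variable columns.
#' @param lineages Two lineage labels (default `c("dicot", "monocot")`).
#' @param fixed_lineage Which lineage is fixed at fixed/variable sites.
#' @param code A [genetic_code()].
#' @param seed Optional integer seed (sets the session RNG).
#' @return List of class `lineage_simulation` with elements `codon_aln`
#'   ([codon_alignment()]), `protein_aln` ([protein_alignment()]),
#'   `partition` ([lineage_partition()]), `cds` (named CDS vector),
#'   `truth` (list: `ancestor`, `sites` data.frame of injected columns
#'   with category and realized residue sets, `config`).
#' @export
simulate_lineages <- function(n_per_lineage = c(8L, 15L), n_codons = 423L,
                              depth_within = c(1.1, 0.9),
                              depth_split = 1.7, omega = 0.1,
                              gc3 = c(0.41, 0.87),
                              n_dimorphic_sites = 1L,
                              n_fixed_variable_sites = 3L,
                              lineages = c("dicot", "monocot"),
                              fixed_lineage = lineages[1],
                              code = genetic_code(), seed = NULL) {
  stopifnot(length(n_per_lineage) == 2L, all(n_per_lineage >= 1L),
            n_codons >= 1L, length(lineages) == 2L,
            all(gc3 > 0 & gc3 < 1), omega >= 0,
            n_dimorphic_sites >= 0L, n_fixed_variable_sites >= 0L,
            fixed_lineage %in% lineages)
  n_inject <- n_dimorphic_sites + n_fixed_variable_sites
  if (n_inject > n_codons)
    stop("more injected sites than codons")
  depth_within <- rep_len(depth_within, 2L)
  if (!is.null(seed)) set.seed(seed)
  nbinfo <- codon_neighbours(code)
  tab <- code$table

  gc_mid <- mean(gc3)
  base3 <- substr(nbinfo$sense, 3, 3)
  w_anc <- ifelse(base3 %in% c("G", "C"), gc_mid, 1 - gc_mid)
  ancestor <- sample(nbinfo$sense, n_codons, replace = TRUE, prob = w_anc)

  ids <- c(paste0(lineages[1], "_", sprintf("%02d", seq_len(n_per_lineage[1]))),
           paste0(lineages[2], "_", sprintf("%02d", seq_len(n_per_lineage[2]))))
  labels <- setNames(rep(lineages, n_per_lineage), ids)

  tips <- vector("list", length(ids)); names(tips) <- ids
  for (g in 1:2) {
    lin_anc <- evolve_codons(ancestor, depth_split, omega, gc3[g], nbinfo)
    for (id in ids[labels == lineages[g]])
      tips[[id]] <- evolve_codons(lin_anc, depth_within[g], omega, gc3[g],
                                  nbinfo)
  }

  # inject lineage-fixed sites last so they are exact by construction
  site_rows <- list()
  if (n_inject > 0L) {
    cols <- sample.int(n_codons, n_inject)
    dim_cols <- cols[seq_len(n_dimorphic_sites)]
    fv_cols <- cols[seq_len(n_fixed_variable_sites) + n_dimorphic_sites]
    var_lineage <- setdiff(lineages, fixed_lineage)
    lin_sorted <- sort(lineages)
    for (col in dim_cols) {
      res <- sample(AMINO_ACIDS, 2L)
      res_by_lin <- setNames(res, lineages)
      for (g in 1:2) {
        codon <- codon_for(res_by_lin[[lineages[g]]], gc3[g], tab)
        for (id in ids[labels == lineages[g]]) tips[[id]][col] <- codon
      }
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        column = col, category = "strictly_dimorphic",
        res_1 = res_by_lin[[lin_sorted[1]]],
        res_2 = res_by_lin[[lin_sorted[2]]],
        stringsAsFactors = FALSE)
    }
    gc3_by_lin <- setNames(gc3, lineages)
    for (col in fv_cols) {
      rf <- sample(AMINO_ACIDS, 1L)
      k <- sample(2:4, 1L)
      vres <- sample(setdiff(AMINO_ACIDS, rf), k)
      fixed_codon <- codon_for(rf, gc3_by_lin[[fixed_lineage]], tab)
      for (id in ids[labels == fixed_lineage]) tips[[id]][col] <- fixed_codon
      var_ids <- ids[labels == var_lineage]
      assigned <- rep_len(vres, length(var_ids))
      for (m in seq_along(var_ids))
        tips[[var_ids[m]]][col] <-
          codon_for(assigned[m], gc3_by_lin[[var_lineage]], tab)
      realized <- setNames(
        list(rf, sort(unique(assigned))),
        c(fixed_lineage, var_lineage))
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        column = col,
        category = paste0("fixed_in_", fixed_lineage,
                          "_variable_in_", var_lineage),
        res_1 = paste(realized[[lin_sorted[1]]], collapse = ", "),
        res_2 = paste(realized[[lin_sorted[2]]], collapse = ", "),
        stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(column = integer(0), category = character(0),
               res_1 = character(0), res_2 = character(0))
  lin_sorted <- sort(lineages)
  names(sites)[names(sites) == "res_1"] <- paste0("residues_", lin_sorted[1])
  names(sites)[names(sites) == "res_2"] <- paste0("residues_", lin_sorted[2])

  cds <- vapply(tips, paste, character(1), collapse = "")
  codon_aln <- codon_alignment(cds)
  protein_aln <- protein_alignment(translate_cds(cds, code))
  structure(list(
    codon_aln = codon_aln,
    protein_aln = protein_aln,
    partition = lineage_partition(labels),
    cds = seq_set(cds, "cds"),
    truth = list(
      ancestor = paste(ancestor, collapse = ""),
      sites = sites,
      config = list(n_per_lineage = n_per_lineage, n_codons = n_codons,
                    depth_within = depth_within, depth_split = depth_split,
                    omega = omega, gc3 = gc3,
                    n_dimorphic_sites = n_dimorphic_sites,
                    n_fixed_variable_sites = n_fixed_variable_sites,
                    lineages = lineages, fixed_lineage = fixed_lineage,
                    seed = seed))),
    class = "lineage_simulation")
}

#' @export
print.lineage_simulation <- function(x, ...) {
  cfg <- x$truth$config
  cat("lineage_simulation:", sum(cfg$n_per_lineage), "sequences x",
      cfg$n_codons, "codons; omega =", cfg$omega, "\n")
  invisible(x)
}

#' Precision and recall of lineage-site detection against simulation truth
#'
#' Compares the columns a classifier assigned to each injected category
#' against the simulator's ground truth, per category.
#'
#' @param truth The `truth` element of a [simulate_lineages()] result.
#' @param detected A [classify_lineage_sites()] data.frame.
#' @return data.frame with `category`, `n_truth`, `n_detected`,
#'   `true_positive`, `precision`, `recall`. Precision is `NA` when
#'   nothing was detected for a category that has truth columns.
#' @export
evaluate_detection <- function(truth, detected) {
  cats <- unique(truth$sites$category)
  rows <- lapply(cats, function(cat) {
    tcols <- truth$sites$column[truth$sites$category == cat]
    dcols <- detected$column[detected$category == cat]
    tp <- length(intersect(tcols, dcols))
    data.frame(category = cat,
               n_truth = length(tcols),
               n_detected = length(dcols),
               true_positive = tp,
               precision = if (length(dcols)) tp / length(dcols)
                           else if (length(tcols)) NA_real_ else 1,
               recall = if (length(tcols)) tp / length(tcols) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = character(0), n_truth = integer(0),
                      n_detected = integer(0), true_positive = integer(0),
                      precision = numeric(0), recall = numeric(0))
  out
}
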