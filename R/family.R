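#' Family and subfamily identity thresholds
#'
#' Nomenclature-committee style cut-offs: proteins sharing more than
#' `family` percent identity belong to one family and more than `subfamily`
#' percent to one subfamily. Both are strict (`>`) comparisons.
#'
#' @param family Minimum family identity, percent (default 40).
#' @param subfamily Minimum subfamily identity, percent (default 60).
#' @return List of class `agnc_thresholds`.
#' @export
agnc_thresholds <- function(family = 40, subfamily = 60) {
  if (!(family > 0 && family < subfamily && subfamily <= 100))
    stop("need 0 < family < subfamily <= 100")
  structure(list(family = family, subfamily = subfamily),
            class = "agnc_thresholds")
}

# Single-linkage connected components of ids whose pairwise value exceeds
# `threshold` (strict). Returns an integer cluster label per id, clusters
# numbered by their lexicographically smallest member id.
threshold_components <- function(identity, threshold, ids = rownames(identity)) {
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (identity[ids[i], ids[j]] > threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_min <- tapply(ids, roots, function(m) min(m))
  order_of <- rank(comp_min[as.character(sort(unique(roots)))])
  labels <- setNames(order_of[as.character(roots)], ids)
  as.integer(labels) |> setNames(ids)
}

#' Assign sequences to families and subfamilies by identity thresholds
#'
#' Families are the connected components of the graph joining sequence
#' pairs whose percent identity strictly exceeds the family threshold
#' (single-linkage clustering, the weakest consistent reading of the
#' pairwise nomenclature rule); subfamilies are components at the subfamily
#' threshold inside each family, so the subfamily partition always refines
#' the family partition. Cluster ids are deterministic: numbered by the
#' lexicographically smallest member id.
#'
#' @param records Named character vector of ungapped protein sequences, or
#'   `NULL` when `identity` is supplied directly.
#' @param thresholds An [agnc_thresholds()].
#' @param identity Optional precomputed symmetric percent-identity matrix
#'   with dimnames; computed with [identity_matrix()] from `records` when
#'   absent.
#' @param ... Passed to [identity_matrix()].
#' @return Object of class `family_assignment`: list with `assignment`
#'   (data.frame id / family / subfamily), `families` and `subfamilies`
#'   (lists of member ids), `identity`, `thresholds`.
#' @export
assign_families <- function(records = NULL, thresholds = agnc_thresholds(),
                            identity = NULL, ...) {
  if (is.null(identity)) {
    if (is.null(records) || length(records) < 1L)
      stop("need at least one sequence record")
    identity <- identity_matrix(records, ...)
  }
  ids <- rownames(identity)
  if (is.null(ids) || !identical(ids, colnames(identity)))
    stop("identity matrix must have matching dimnames")
  fam <- threshold_components(identity, thresholds$family)
  sub <- integer(length(ids)); names(sub) <- ids
  next_sub <- 0L
  for (f in sort(unique(fam))) {
    members <- ids[fam == f]
    subm <- threshold_components(
      identity[members, members, drop = FALSE], thresholds$subfamily,
      ids = members)
    sub[members] <- subm + next_sub
    next_sub <- next_sub + max(subm)
  }
  assignment <- data.frame(id = ids,
                           family = unname(fam[ids]),
                           subfamily = unname(sub[ids]),
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    assignment = assignment,
    families = split(assignment$id, assignment$family),
    subfamilies = split(assignment$id, assignment$subfamily),
    identity = identity,
    thresholds = thresholds), class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("family_assignment:", nrow(x$assignment), "sequences,",
      length(x$families), "families,",
      length(x$subfamilies), "subfamilies\n")
  invisible(x)
}

#' Family frequency ratios
#'
#' The ratio of the number of genes in each family to the total number of
#' genes in the set; ratios sum to one.
#'
#' @param assignment A [assign_families()] result.
#' @return data.frame with columns `family`, `n`, `ratio`.
#' @export
family_frequencies <- function(assignment) {
  stopifnot(inherits(assignment, "family_assignment"))
  n <- vapply(assignment$families, length, integer(1))
  data.frame(family = as.integer(names(n)),
             n = unname(n),
             ratio = unname(n) / sum(n),
             row.names = NULL)
}
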