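#' Percent identity of two protein sequences
#'
#' Computes a deterministic global (Needleman-Wunsch) alignment with a
#' BLOSUM62 substitution matrix and affine gap costs, then reports
#' `100 * matches / denominator`. Terminal-gap columns (end overhangs of the
#' shorter sequence) are excluded from the default denominator, so identity
#' reflects the aligned span; the alternative denominator is the shorter
#' sequence length. Ambiguous residues (`X`) always count as mismatches.
#'
#' @param a,b Ungapped protein sequence strings.
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (defaults 10 and 0.5).
#' @param denominator `"alignment"` (aligned columns minus terminal-gap
#'   columns, default) or `"shorter"` (length of the shorter sequence).
#' @return Percent identity in `[0, 100]`; symmetric in `a` and `b`.
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 90
#' @export
pairwise_identity <- function(a, b, substitution_matrix = "BLOSUM62",
                              gap_open = 10, gap_extend = 0.5,
                              denominator = c("alignment", "shorter")) {
  denominator <- match.arg(denominator)
  a <- toupper(as.character(a)[1])
  b <- toupper(as.character(b)[1])
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | sa == "-"
  n <- length(gap)
  keep <- rep(TRUE, n)
  i <- 1L
  while (i <= n && gap[i]) { keep[i] <- FALSE; i <- i + 1L }
  i <- n
  while (i >= 1L && gap[i]) { keep[i] <- FALSE; i <- i - 1L }
  matches <- pa == sa & !gap & pa != "X"
  denom <- switch(denominator,
                  alignment = sum(keep),
                  shorter = min(nchar(a), nchar(b)))
  100 * sum(matches & keep) / denom
}

#' Pairwise identity matrix for a set of proteins
#'
#' @param x Named character vector of ungapped protein sequences.
#' @param ... Passed to [pairwise_identity()].
#' @return Symmetric numeric matrix of percent identities, diagonal 100.
#' @export
identity_matrix <- function(x, ...) {
  ids <- names(x)
  if (is.null(ids) || anyDuplicated(ids))
    stop("sequences must have unique names")
  n <- length(x)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- pairwise_identity(x[[i]], x[[j]], ...)
      }
    }
  }
  m
}
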