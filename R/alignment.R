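#' Protein alignment container
#'
#' Stores a gapped protein alignment as a character matrix (one row per
#' sequence, one column per alignment position). Column indices are 1-based
#' and, after filtering, the original column numbers are retained in
#' `$columns` so sites can always be reported in the coordinates of the
#' input alignment.
#'
#' @param x Named character vector of equal-length gapped protein strings.
#' @return An object of class `protein_alignment`: list with `matrix`
#'   (characters, rownames = ids) and `columns` (original column indices).
#' @export
protein_alignment <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("alignment sequences must be named")
  ids <- names(x)
  x <- setNames(toupper(as.character(x)), ids)
  w <- unique(nchar(x))
  if (length(w) != 1L)
    stop("gapped sequences have unequal lengths: ",
         paste(w, collapse = ", "))
  m <- do.call(rbind, strsplit(x, "", fixed = TRUE))
  rownames(m) <- ids
  structure(list(matrix = m, columns = seq_len(ncol(m))),
            class = "protein_alignment")
}

#' Codon alignment container
#'
#' @param x Named character vector of equal-length gapped codon strings
#'   (length a multiple of 3; a fully gapped codon is `"---"`).
#' @return An object of class `codon_alignment`: list with `matrix`
#'   (3-letter codon strings) and `columns` (original codon-column indices).
#' @export
codon_alignment <- function(x) {
  if (is.null(names(x))) stop("alignment sequences must be named")
  x <- setNames(toupper(as.character(x)), names(x))
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("gapped sequences have unequal lengths")
  if (w %% 3L != 0L) stop("codon alignment width must be a multiple of 3")
  rows <- lapply(x, split_codons)
  m <- do.call(rbind, rows)
  rownames(m) <- names(x)
  structure(list(matrix = m, columns = seq_len(ncol(m))),
            class = "codon_alignment")
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("protein_alignment:", nrow(x$matrix), "sequences x",
      ncol(x$matrix), "columns\n")
  invisible(x)
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", nrow(x$matrix), "sequences x",
      ncol(x$matrix), "codon columns\n")
  invisible(x)
}

#' Alignment rows as gapped strings
#'
#' @param x A `protein_alignment` or `codon_alignment`.
#' @return Named character vector of gapped row strings.
#' @export
alignment_strings <- function(x) {
  apply(x$matrix, 1L, paste, collapse = "")
}

#' Number of sequences in an alignment
#' @param x A `protein_alignment` or `codon_alignment`.
#' @return Integer.
#' @export
n_sequences <- function(x) nrow(x$matrix)

ungap <- function(s) gsub("-", "", s, fixed = TRUE)

#' Expand a codon alignment to a nucleotide character matrix
#'
#' @param x A `codon_alignment`.
#' @return List with `matrix` (n x 3L nucleotide characters) and `position`
#'   (codon position 1/2/3 of each nucleotide column).
#' @export
as_nucleotide_matrix <- function(x) {
  stopifnot(inherits(x, "codon_alignment"))
  L <- ncol(x$matrix)
  nt <- matrix("", nrow = nrow(x$matrix), ncol = 3L * L,
               dimnames = list(rownames(x$matrix), NULL))
  for (p in 1:3)
    nt[, seq(p, 3L * L, by = 3L)] <- substr(x$matrix, p, p)
  list(matrix = nt, position = rep(1:3, L))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Threads each unaligned CDS through its gapped protein row: every protein
#' gap becomes `"---"` and every residue column becomes the corresponding
#' source codon, in order (pal2nal-style construction). The CDS must
#' translate exactly to the ungapped protein row (a terminal stop codon on
#' the CDS is allowed and ignored).
#'
#' @param alignment A [protein_alignment()].
#' @param cds Named character vector of CDS sequences covering every
#'   alignment id.
#' @param code A [genetic_code()].
#' @return A [codon_alignment()] with one codon column per protein column.
#' @export
back_translate <- function(alignment, cds, code = genetic_code()) {
  stopifnot(inherits(alignment, "protein_alignment"))
  ids <- rownames(alignment$matrix)
  missing <- setdiff(ids, names(cds))
  if (length(missing))
    stop("missing CDS for: ", paste(missing, collapse = ", "))
  L <- ncol(alignment$matrix)
  out <- matrix("---", nrow = length(ids), ncol = L,
                dimnames = list(ids, NULL))
  for (id in ids) {
    row <- alignment$matrix[id, ]
    res_at <- which(row != "-")
    prot <- row[res_at]
    tr <- strsplit(translate_cds(setNames(cds[[id]], id), code), "",
                   fixed = TRUE)[[1]]
    if (length(tr) != length(prot))
      stop("CDS/protein length mismatch for '", id, "': CDS translates to ",
           length(tr), " residues, alignment row has ", length(prot))
    mism <- which(tr != prot)
    if (length(mism))
      stop("CDS/protein mismatch for '", id, "' at residue ", mism[1],
           " (CDS gives '", tr[mism[1]], "', alignment has '",
           prot[mism[1]], "')")
    codons <- split_codons(toupper(cds[[id]]))[seq_along(prot)]
    out[id, res_at] <- codons
  }
  structure(list(matrix = out, columns = alignment$columns),
            class = "codon_alignment")
}

#' Partial-deletion gap filter
#'
#' Removes alignment columns whose non-gap fraction falls below a site
#' coverage threshold (the "partial deletion" option with, e.g., a 95%
#' cut-off). Codon columns are treated atomically: a codon containing any
#' gap character counts as a gap. Ambiguous residues/bases (X, N) count as
#' non-gap coverage. The returned object keeps the surviving original
#' column indices in `$columns` and the per-column keep mask in the
#' `column_mask` attribute.
#'
#' @param x A `protein_alignment` or `codon_alignment`.
#' @param coverage Minimum non-gap fraction in `[0, 1]` (default 0.95).
#' @return Filtered alignment of the same class.
#' @export
partial_deletion <- function(x, coverage = 0.95) {
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  UseMethod("partial_deletion")
}

partial_deletion_impl <- function(x, coverage, is_gap) {
  frac <- 1 - colMeans(is_gap)
  keep <- frac >= coverage
  if (!any(keep))
    warning("partial deletion at coverage ", coverage,
            " removed every column")
  out <- x
  out$matrix <- x$matrix[, keep, drop = FALSE]
  out$columns <- x$columns[keep]
  attr(out, "column_mask") <- keep
  out
}

#' @export
partial_deletion.protein_alignment <- function(x, coverage = 0.95) {
  partial_deletion_impl(x, coverage, x$matrix == "-")
}

#' @export
partial_deletion.codon_alignment <- function(x, coverage = 0.95) {
  gap <- matrix(grepl("-", x$matrix, fixed = TRUE), nrow = nrow(x$matrix))
  partial_deletion_impl(x, coverage, gap)
}
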