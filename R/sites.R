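#' Two-lineage partition of sequence ids
#'
#' @param labels Named character vector mapping sequence id to lineage
#'   label; exactly two distinct labels are required. Lineage order is
#'   alphabetical and is used consistently in all two-group reports.
#' @return Named character vector of class `lineage_partition` with
#'   attribute `lineages` (the two labels, sorted).
#' @export
lineage_partition <- function(labels) {
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("partition labels must be named by sequence id")
  if (anyDuplicated(names(labels)))
    stop("duplicate sequence id(s) in partition")
  labels <- setNames(as.character(labels), names(labels))
  lin <- sort(unique(labels))
  if (length(lin) != 2L)
    stop("partition must contain exactly two lineage labels, got: ",
         paste(lin, collapse = ", "))
  sizes <- table(labels)
  if (any(sizes < 2L))
    warning("lineage group(s) with fewer than 2 members: ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
  structure(labels, lineages = lin, class = "lineage_partition")
}

#' Read a two-column id/lineage partition file
#'
#' @param path Tab-separated file: column 1 sequence id, column 2 lineage
#'   label; no header, `#` comment lines ignored.
#' @return A [lineage_partition()].
#' @export
read_partition <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("partition file must have two columns")
  lineage_partition(setNames(as.character(df[[2]]), as.character(df[[1]])))
}

# ids of one lineage, in alignment order
partition_ids <- function(partition, lineage, ids) {
  ids[ids %in% names(partition)[partition == lineage]]
}

check_partition_covers <- function(partition, ids) {
  missing <- setdiff(ids, names(partition))
  if (length(missing))
    stop("partition does not cover alignment id(s): ",
         paste(missing, collapse = ", "))
}

states_of <- function(column, alphabet) column[column %in% alphabet]

#' Parsimony-informative sites of an alignment
#'
#' A column is parsimony-informative when it shows at least two distinct
#' states, each carried by at least two sequences. Gaps and ambiguous
#' characters (anything outside the 20 amino acids, or outside A/C/G/T for
#' nucleotides) are never counted as states.
#'
#' @param x A `protein_alignment`, or a `codon_alignment` (scored on its
#'   nucleotide expansion), or a plain character matrix.
#' @param alphabet State alphabet for a plain matrix input; inferred for
#'   alignment classes.
#' @return Integer vector of informative column indices (1-based, in the
#'   coordinates of the current alignment view).
#' @export
parsimony_informative_sites <- function(x, alphabet = NULL) {
  if (inherits(x, "protein_alignment")) {
    m <- x$matrix; alphabet <- AMINO_ACIDS
  } else if (inherits(x, "codon_alignment")) {
    m <- as_nucleotide_matrix(x)$matrix; alphabet <- NUCLEOTIDES
  } else {
    m <- x
    if (is.null(alphabet)) stop("alphabet required for matrix input")
  }
  if (nrow(m) < 4L)
    stop("parsimony informativeness needs at least 4 sequences")
  informative <- vapply(seq_len(ncol(m)), function(j) {
    tab <- table(states_of(m[, j], alphabet))
    sum(tab >= 2L) >= 2L
  }, logical(1))
  which(informative)
}

# order residues by descending frequency, ties alphabetical
format_residues <- function(chars) {
  if (length(chars) == 0L) return("")
  tab <- table(chars)
  ord <- order(-as.integer(tab), names(tab))
  paste(names(tab)[ord], collapse = ", ")
}

#' Classify alignment columns by lineage polymorphism pattern
#'
#' For each requested column the residue sets of the two lineages are
#' compared (gaps and ambiguous residues excluded). Categories:
#' * `invariant` - a single residue across both lineages;
#' * `non_informative` - one lineage contributes no residue (all gap);
#' * `overlapping` - the lineage residue sets share at least one residue
#'   but are not identical singletons;
#' * `strictly_dimorphic` - each lineage fixed for a single residue and the
#'   two residues differ;
#' * `fixed_in_<A>_variable_in_<B>` - disjoint sets, one lineage fixed, the
#'   other variable;
#' * `disjoint` - disjoint sets, both lineages variable.
#'
#' The default site universe is the parsimony-informative columns of the
#' protein alignment; `sites = "all"` classifies every column instead.
#' Residue sets are reported ordered by descending frequency, ties broken
#' alphabetically (e.g. `"T, G, S"`).
#'
#' @param alignment A [protein_alignment()].
#' @param partition A [lineage_partition()] covering every alignment id.
#' @param sites `"informative"` (default) or `"all"`.
#' @param columns Optional explicit column indices (current view,
#'   1-based); overrides `sites`.
#' @return data.frame of class `site_classification` with columns `column`
#'   (original alignment coordinates), `informative`, one residue-set
#'   column per lineage (`residues_<label>`), and `category`. Attribute
#'   `lineages` stores the two labels.
#' @export
classify_lineage_sites <- function(alignment, partition,
                                   sites = c("informative", "all"),
                                   columns = NULL) {
  stopifnot(inherits(alignment, "protein_alignment"))
  sites <- match.arg(sites)
  m <- alignment$matrix
  check_partition_covers(partition, rownames(m))
  lin <- attr(partition, "lineages")
  idsA <- partition_ids(partition, lin[1], rownames(m))
  idsB <- partition_ids(partition, lin[2], rownames(m))
  if (is.null(columns)) {
    columns <- if (sites == "informative")
      parsimony_informative_sites(alignment) else seq_len(ncol(m))
  } else {
    if (any(columns < 1L | columns > ncol(m)))
      stop("column index out of range (alignment has ", ncol(m),
           " columns)")
  }
  rows <- lapply(columns, function(j) {
    resA <- states_of(m[idsA, j], AMINO_ACIDS)
    resB <- states_of(m[idsB, j], AMINO_ACIDS)
    setA <- unique(resA); setB <- unique(resB)
    category <- if (length(setA) == 0L || length(setB) == 0L) {
      warning("lineage with no residue at column ", alignment$columns[j])
      "non_informative"
    } else if (length(union(setA, setB)) == 1L) {
      "invariant"
    } else if (length(intersect(setA, setB)) > 0L) {
      "overlapping"
    } else if (length(setA) == 1L && length(setB) == 1L) {
      "strictly_dimorphic"
    } else if (length(setA) == 1L) {
      paste0("fixed_in_", lin[1], "_variable_in_", lin[2])
    } else if (length(setB) == 1L) {
      paste0("fixed_in_", lin[2], "_variable_in_", lin[1])
    } else {
      "disjoint"
    }
    data.frame(column = alignment$columns[j],
               informative = NA,  # filled below
               resA = format_residues(resA),
               resB = format_residues(resB),
               category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), informative = logical(0),
                      resA = character(0), resB = character(0),
                      category = character(0))
  }
  inf_cols <- if (nrow(m) >= 4L) parsimony_informative_sites(alignment)
              else integer(0)
  out$informative <- out$column %in% alignment$columns[inf_cols]
  names(out)[names(out) == "resA"] <- paste0("residues_", lin[1])
  names(out)[names(out) == "resB"] <- paste0("residues_", lin[2])
  attr(out, "lineages") <- lin
  class(out) <- c("site_classification", "data.frame")
  out
}

#' Map an alignment column to a residue number within one sequence
#'
#' Counts non-gap characters of the chosen row up to and including the
#' column, i.e. the 1-based position of the residue within the ungapped
#' sequence (the per-isoform numbering used when reporting sites like
#' "Y465" versus "F464" from one shared alignment column).
#'
#' @param alignment A [protein_alignment()].
#' @param id Sequence id.
#' @param column Column index (current view, 1-based).
#' @return Integer residue number.
#' @export
column_to_residue_number <- function(alignment, id, column) {
  stopifnot(inherits(alignment, "protein_alignment"))
  if (!id %in% rownames(alignment$matrix)) stop("unknown id: ", id)
  if (column < 1L || column > ncol(alignment$matrix))
    stop("column out of range")
  row <- alignment$matrix[id, ]
  if (row[column] == "-")
    stop("sequence '", id, "' has a gap at column ", column)
  sum(row[seq_len(column)] != "-")
}
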