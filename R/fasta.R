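#' Read sequences from a FASTA file
#'
#' Reads protein or CDS FASTA (aligned input with `-` gaps is preserved).
#' The sequence id is the first whitespace-delimited token of the header;
#' duplicate ids and empty files are errors.
#'
#' @param path Path to a FASTA file.
#' @param kind `"protein"` or `"cds"`.
#' @return A named character vector of uppercased sequences, class `seq_set`,
#'   with attribute `kind`.
#' @export
read_fasta <- function(path, kind = c("protein", "cds")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  x <- toupper(as.character(set))
  names(x) <- ids
  seq_set(x, kind)
}

seq_set <- function(x, kind) {
  structure(as.character(x),
            names = names(x), kind = kind, class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat("seq_set of", length(x), attr(x, "kind"), "sequences; lengths",
      min(nchar(x)), "-", max(nchar(x)), "\n")
  invisible(x)
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences (e.g. a `seq_set`).
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(as.character(x), names(x)))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}
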