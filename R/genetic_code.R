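#' Genetic code table
#'
#' Wraps an NCBI translation table as a named character vector over the 64
#' codons, with `"*"` marking stop codons. Table 1 (the standard code) is the
#' default everywhere in the package.
#'
#' @param id NCBI genetic-code table id (integer, default 1).
#' @return An object of class `genetic_code`: list with elements `table`
#'   (named character vector, codon -> amino-acid letter or `"*"`) and `id`.
#' @examples
#' code <- genetic_code()
#' code$table[["ATG"]]  # "M"
#' @export
genetic_code <- function(id = 1L) {
  tab <- Biostrings::getGeneticCode(as.character(id))
  if (length(tab) != 64L)
    stop("genetic code table ", id, " does not define all 64 codons")
  structure(list(table = tab, id = as.integer(id)), class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code table", x$id, "(",
      sum(x$table == "*"), "stop codons )\n")
  invisible(x)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  if (n == 0L) return(character(0))
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence
#'
#' Translates CDS strings codon by codon. A terminal stop codon is dropped;
#' an internal stop is an error reporting the codon index. Codons containing
#' characters outside A/C/G/T (ambiguity codes, gaps) translate to `"X"`.
#'
#' @param cds Character vector of CDS strings (optionally named).
#' @param code A [genetic_code()].
#' @return Character vector of protein sequences, names preserved.
#' @examples
#' translate_cds("ATGGGGAAA")  # "MGK"
#' translate_cds("ATGTAA")     # "M" (terminal stop dropped)
#' @export
translate_cds <- function(cds, code = genetic_code()) {
  tab <- code$table
  out <- vapply(seq_along(cds), function(i) {
    s <- toupper(as.character(cds[[i]]))
    id <- if (!is.null(names(cds))) names(cds)[i] else paste0("sequence ", i)
    if (nchar(s) %% 3L != 0L)
      stop("CDS length of '", id, "' (", nchar(s),
           ") is not a multiple of 3")
    codons <- split_codons(s)
    aa <- tab[codons]
    aa[is.na(aa)] <- "X"
    stops <- which(aa == "*")
    internal <- stops[stops < length(codons)]
    if (length(internal))
      stop("internal stop codon in '", id, "' at codon ", internal[1])
    if (length(stops) && stops[length(stops)] == length(codons))
      aa <- aa[-length(aa)]
    paste(aa, collapse = "")
  }, character(1))
  names(out) <- names(cds)
  out
}
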