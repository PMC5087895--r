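tajima_coefficients <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D neutrality statistic
#'
#' Contrasts the mean number of pairwise nucleotide differences with the
#' number of segregating sites (Tajima 1989):
#' `D = (kbar - S/a1) / sqrt(e1*S + e2*S*(S-1))`, with the usual
#' coefficients `a1 = sum 1/i`, `a2 = sum 1/i^2`, `b1 = (n+1)/(3(n-1))`,
#' `b2 = 2(n^2+n+3)/(9n(n-1))`, `c1 = b1 - 1/a1`,
#' `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`. Diversity `pi = kbar/L` and Watterson's
#' `theta_W = S/(a1 L)` are reported per site. The default `complete`
#' deletion drops every column containing a gap or ambiguous base before
#' counting; `pairwise` deletion counts segregating sites over the
#' non-gap states of each column and mean differences over the columns
#' shared by each pair (an approximation, since the site universe then
#' differs between pairs).
#'
#' @param x A nucleotide alignment: named character vector of equal-length
#'   gapped strings, a character matrix, or a [codon_alignment()] (expanded
#'   to nucleotides).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return List of class `tajima_d`: `n`, `L` (analysed sites), `S`,
#'   `k` (mean pairwise differences), `pi`, `theta` (both per site), `D`,
#'   `coefficients`, `flags`. `S = 0` gives `D = NA` with `pi` and
#'   `theta` 0, flagged `no_segregating_sites`.
#' @export
tajimas_d <- function(x, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  if (inherits(x, "codon_alignment")) {
    m <- as_nucleotide_matrix(x)$matrix
  } else if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("sequences have unequal lengths")
    m <- do.call(rbind, strsplit(toupper(as.character(x)), "", fixed = TRUE))
    rownames(m) <- names(x)
  }
  n <- nrow(m)
  if (n < 4L) stop("Tajima's D needs at least 4 sequences")
  co <- tajima_coefficients(n)
  valid <- matrix(m %in% NUCLEOTIDES, nrow = n)
  flags <- character(0)

  if (deletion == "complete") {
    keep <- colSums(valid) == n
    if (!any(keep)) stop("complete deletion removed every site")
    mm <- m[, keep, drop = FALSE]
    L <- ncol(mm)
    S <- sum(apply(mm, 2, function(col) length(unique(col))) > 1L)
    pairs <- combn(n, 2)
    diffs <- apply(pairs, 2, function(p) sum(mm[p[1], ] != mm[p[2], ]))
    kbar <- mean(diffs)
  } else {
    L <- ncol(m)
    S <- sum(apply(m, 2, function(col) {
      st <- unique(col[col %in% NUCLEOTIDES])
      length(st) > 1L
    }))
    pairs <- combn(n, 2)
    diffs <- apply(pairs, 2, function(p) {
      ok <- valid[p[1], ] & valid[p[2], ]
      sum(m[p[1], ok] != m[p[2], ok])
    })
    kbar <- mean(diffs)
  }

  pi <- kbar / L
  theta <- S / (co$a1 * L)
  if (S == 0) {
    D <- NA_real_
    flags <- c(flags, "no_segregating_sites")
    pi <- 0; theta <- 0
  } else {
    D <- (kbar - S / co$a1) / sqrt(co$e1 * S + co$e2 * S * (S - 1))
  }
  structure(list(n = n, L = L, S = S, k = kbar, pi = pi, theta = theta,
                 D = D, coefficients = co, deletion = deletion,
                 flags = flags), class = "tajima_d")
}

#' @export
print.tajima_d <- function(x, ...) {
  cat(sprintf(
    "Tajima's D: n = %d, L = %d, S = %d, k = %.4f, pi = %.4f, theta = %.4f, D = %s\n",
    x$n, x$L, x$S, x$k, x$pi, x$theta,
    if (is.na(x$D)) "NA" else sprintf("%.4f", x$D)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
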