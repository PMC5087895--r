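# Nei-Gojobori (1986) codon counting machinery.
#
# Synonymous site fractions and per-codon-pair synonymous/nonsynonymous
# difference counts are precomputed once per genetic code and cached:
# - s[codon]: sum over the three positions of the fraction of single-base
#   changes that are synonymous, counting only changes that do not create a
#   stop codon, so s + n = 3 for every sense codon.
# - SD/ND[codon a, codon b]: synonymous / nonsynonymous differences,
#   averaged over all minimal mutational pathways between a and b;
#   pathways passing through a stop codon are excluded (all pathways are
#   used as a fallback in the rare case every pathway is blocked).

.ng_cache <- new.env(parent = emptyenv())

permutations_of <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in permutations_of(v[-i]))
      out <- c(out, list(c(v[i], rest)))
  out
}

ng_tables <- function(code = genetic_code()) {
  key <- as.character(code$id)
  cached <- get0(key, envir = .ng_cache)
  if (!is.null(cached)) return(cached)
  tab <- code$table
  codons <- names(tab)
  mat <- do.call(rbind, strsplit(codons, "", fixed = TRUE))
  rownames(mat) <- codons

  neighbours_at <- function(codon, pos) {
    alt <- setdiff(NUCLEOTIDES, mat[codon, pos])
    vapply(alt, function(b) {
      x <- mat[codon, ]; x[pos] <- b; paste(x, collapse = "")
    }, character(1))
  }

  s <- setNames(numeric(64), codons)
  for (codon in codons) {
    if (tab[[codon]] == "*") { s[codon] <- NA_real_; next }
    total <- 0
    for (pos in 1:3) {
      nb <- neighbours_at(codon, pos)
      nb <- nb[tab[nb] != "*"]
      if (length(nb) == 0L) next
      total <- total + mean(tab[nb] == tab[[codon]])
    }
    s[codon] <- total
  }

  path_counts <- function(a, b, exclude_stops = TRUE) {
    d <- which(mat[a, ] != mat[b, ])
    res <- matrix(NA_real_, 0, 2)
    for (ord in permutations_of(d)) {
      cur <- mat[a, ]; sd <- 0; nd <- 0; ok <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- mat[b, pos]
        ncod <- paste(nxt, collapse = "")
        if (exclude_stops && tab[[ncod]] == "*" && ncod != b) {
          ok <- FALSE; break
        }
        ccod <- paste(cur, collapse = "")
        if (tab[[ncod]] == tab[[ccod]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (ok) res <- rbind(res, c(sd, nd))
    }
    res
  }

  SD <- matrix(0, 64, 64, dimnames = list(codons, codons))
  ND <- SD
  sense <- codons[tab != "*"]
  for (a in sense) {
    for (b in sense) {
      if (a >= b) next
      d <- sum(mat[a, ] != mat[b, ])
      if (d == 0L) next
      pc <- path_counts(a, b, exclude_stops = TRUE)
      if (nrow(pc) == 0L) pc <- path_counts(a, b, exclude_stops = FALSE)
      SD[a, b] <- SD[b, a] <- mean(pc[, 1])
      ND[a, b] <- ND[b, a] <- mean(pc[, 2])
    }
  }
  out <- list(s = s, SD = SD, ND = ND, codons = codons, table = tab)
  assign(key, out, envir = .ng_cache)
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - (4/3) * p)`; undefined (`NA`) for `p >= 0.75`.
#'
#' @param p Proportion of differing sites.
#' @return Corrected distance, `NA` where undefined.
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Integer codon indices (into ng table order) for a codon matrix; NA for
# gapped/ambiguous codons and for stop codons.
codon_index_matrix <- function(codon_aln, tables) {
  m <- codon_aln$matrix
  idx <- match(m, tables$codons)
  idx[!is.na(idx) & tables$table[idx] == "*"] <- NA_integer_
  matrix(idx, nrow = nrow(m), dimnames = dimnames(m))
}

# Per-column sd/nd/s contributions for one sequence pair (NA where either
# codon is missing/stop).
ng_pair_profile <- function(ia, ib, tables) {
  valid <- !is.na(ia) & !is.na(ib)
  sd <- nd <- s <- rep(NA_real_, length(ia))
  if (any(valid)) {
    sd[valid] <- tables$SD[cbind(ia[valid], ib[valid])]
    nd[valid] <- tables$ND[cbind(ia[valid], ib[valid])]
    s[valid] <- (tables$s[ia[valid]] + tables$s[ib[valid]]) / 2
  }
  list(sd = sd, nd = nd, s = s, valid = valid)
}

#' Nei-Gojobori counts for one pair of aligned codon sequences
#'
#' Counts synonymous (`Sd`) and nonsynonymous (`Nd`) differences and
#' synonymous (`S`) / nonsynonymous (`N`) sites over the codon columns
#' shared by the two rows. Columns containing a gap, an ambiguous base or a
#' stop codon in either sequence are excluded. Site fractions exclude
#' single-base changes that would create a stop codon; `S` is averaged over
#' the two sequences, and multi-difference codons average their differences
#' over all minimal mutational pathways (stop-passing pathways excluded).
#'
#' @param a,b Gapped codon strings (lengths equal, multiples of 3).
#' @param code A [genetic_code()].
#' @param correction `"none"` (proportions) or `"jc"` (Jukes-Cantor).
#' @return List of class `ng_pair`: `Sd`, `Nd`, `S`, `N`, `pS`, `pN`,
#'   `dS`, `dN`, `n_codons` (compared columns) and `flags` (e.g. when the
#'   Jukes-Cantor correction is undefined at `p >= 0.75`).
#' @examples
#' ng <- nei_gojobori_pair("GGGAAA", "GGAAAA")
#' ng$S   # 4/3
#' ng$pS  # 0.75
#' @export
nei_gojobori_pair <- function(a, b, code = genetic_code(),
                              correction = c("none", "jc")) {
  correction <- match.arg(correction)
  tables <- ng_tables(code)
  ca <- split_codons(toupper(as.character(a)))
  cb <- split_codons(toupper(as.character(b)))
  if (length(ca) != length(cb))
    stop("codon rows have different lengths")
  ia <- match(ca, tables$codons)
  ib <- match(cb, tables$codons)
  ia[!is.na(ia) & tables$table[ia] == "*"] <- NA_integer_
  ib[!is.na(ib) & tables$table[ib] == "*"] <- NA_integer_
  prof <- ng_pair_profile(ia, ib, tables)
  n_codons <- sum(prof$valid)
  flags <- character(0)
  if (n_codons == 0L) {
    return(structure(list(Sd = 0, Nd = 0, S = 0, N = 0, pS = NA_real_,
                          pN = NA_real_, dS = NA_real_, dN = NA_real_,
                          n_codons = 0L, flags = "no_comparable_codons"),
                     class = "ng_pair"))
  }
  Sd <- sum(prof$sd[prof$valid])
  Nd <- sum(prof$nd[prof$valid])
  S <- sum(prof$s[prof$valid])
  N <- 3 * n_codons - S
  if (S == 0 && Sd > 0)
    stop("inconsistent counts: synonymous differences without synonymous sites")
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  if (correction == "jc") {
    dS <- jukes_cantor(pS); dN <- jukes_cantor(pN)
    if (is.na(dS) && !is.na(pS)) flags <- c(flags, "dS_undefined_jc")
    if (is.na(dN) && !is.na(pN)) flags <- c(flags, "dN_undefined_jc")
  } else {
    dS <- pS; dN <- pN
  }
  structure(list(Sd = Sd, Nd = Nd, S = S, N = N, pS = pS, pN = pN,
                 dS = dS, dN = dN, n_codons = n_codons, flags = flags),
            class = "ng_pair")
}

#' @export
print.ng_pair <- function(x, ...) {
  cat(sprintf(
    "Nei-Gojobori pair: %d codons; Sd=%.3f Nd=%.3f S=%.3f N=%.3f dS=%.4f dN=%.4f\n",
    x$n_codons, x$Sd, x$Nd, x$S, x$N, x$dS, x$dN))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
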