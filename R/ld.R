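#' Two-locus gamete counts
#'
#' Tallies the four gametes over a pair of markers. A homozygous line
#' contributes one gamete, a phased diploid two (its stored phases). Allele
#' "A"/"B" denotes the minor (coded) allele at the first/second marker.
#'
#' @param gm a complete, phase-resolved [genotype_matrix()].
#' @param marker_a,marker_b marker column indices.
#' @return list of class `gamete_counts` with fields `n_AB`, `n_Ab`, `n_aB`,
#'   `n_ab`, `n_total`.
#' @export
gamete_counts <- function(gm, marker_a, marker_b) {
  g <- gametes(gm, c(marker_a, marker_b))
  counts_from_gametes(g[, 1], g[, 2])
}

counts_from_gametes <- function(a, b) {
  n_AB <- sum(a == 1 & b == 1)
  n_Ab <- sum(a == 1 & b == 0)
  n_aB <- sum(a == 0 & b == 1)
  n_ab <- sum(a == 0 & b == 0)
  structure(list(n_AB = n_AB, n_Ab = n_Ab, n_aB = n_aB, n_ab = n_ab,
                 n_total = n_AB + n_Ab + n_aB + n_ab),
            class = "gamete_counts")
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of the two dosage vectors (composite LD; equal
#' to gametic r-squared in fully homozygous panels).
#'
#' @inheritParams gamete_counts
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(gm, marker_a, marker_b) {
  x <- gm$dosages[, marker_a]; y <- gm$dosages[, marker_b]
  if (anyNA(x) || anyNA(y)) stop("LD requires complete (imputed) genotypes")
  if (sd(x) == 0 || sd(y) == 0)
    stop("LD undefined for a monomorphic marker")
  cor(x, y)^2
}

#' Lewontin's normalized disequilibrium D-prime
#'
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` where `D_max` is
#' `min(p_A p_b, p_a p_B)` for `D > 0` and `min(p_A p_B, p_a p_b)` otherwise.
#'
#' @param counts a [gamete_counts()] object.
#' @return D-prime in `[0, 1]`.
#' @export
compute_dprime <- function(counts) {
  n <- counts$n_total
  if (n <= 0) stop("empty gamete counts")
  pAB <- counts$n_AB / n
  pA <- (counts$n_AB + counts$n_Ab) / n
  pB <- (counts$n_AB + counts$n_aB) / n
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("D-prime undefined for a monomorphic locus")
  D <- pAB - pA * pB
  if (D == 0) return(0)
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  min(abs(D) / Dmax, 1)     # guard the last-ulp overshoot
}

# D-prime straight from two gamete vectors (internal fast path)
dprime_from_gametes <- function(a, b) compute_dprime(counts_from_gametes(a, b))

#' Bootstrap confidence bounds on D-prime
#'
#' Nonparametric percentile bootstrap over individuals (both gametes of a
#' phased diploid are resampled together). Replicates in which either locus
#' collapses to monomorphic are redrawn up to 10 times, then dropped with a
#' warning. Deterministic given `seed`. The replicate D-prime values are
#' attached as attribute `"replicates"`.
#'
#' @inheritParams gamete_counts
#' @param conf confidence level (default 0.95).
#' @param n_boot number of bootstrap replicates (>= 50).
#' @param seed integer seed.
#' @return numeric `c(lower, upper)`.
#' @export
dprime_ci <- function(gm, marker_a, marker_b, conf = 0.95, n_boot = 200, seed) {
  if (n_boot < 50) stop("n_boot must be >= 50")
  g <- gametes(gm, c(marker_a, marker_b))
  a <- g[, 1]; b <- g[, 2]
  if (sd(a) == 0 || sd(b) == 0) stop("D-prime CI undefined for a monomorphic locus")
  n_ind <- n_samples(gm)
  gps <- gametes_per_sample(gm)
  # gamete row indices per individual
  rows <- if (gps == 1L) matrix(seq_len(n_ind), ncol = 1)
          else cbind(seq_len(n_ind), n_ind + seq_len(n_ind))
  dp <- with_seed(seed, {
    draw <- function(k) {
      idx <- matrix(sample.int(n_ind, k * n_ind, replace = TRUE), nrow = k)
      gi <- if (gps == 1L) idx else cbind(idx, n_ind + idx)
      A <- matrix(a[gi], nrow = k); B <- matrix(b[gi], nrow = k)
      nAB <- rowSums(A * B); nAb <- rowSums(A * (1 - B))
      naB <- rowSums((1 - A) * B); nab <- rowSums((1 - A) * (1 - B))
      nt <- nAB + nAb + naB + nab
      pAB <- nAB / nt; pA <- (nAB + nAb) / nt; pB <- (nAB + naB) / nt
      mono <- pA %in% c(0, 1) | pB %in% c(0, 1)
      D <- pAB - pA * pB
      Dmax <- ifelse(D > 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                     pmin(pA * pB, (1 - pA) * (1 - pB)))
      val <- pmin(ifelse(D == 0, 0, abs(D) / Dmax), 1)
      val[mono] <- NA_real_
      val
    }
    out <- draw(n_boot)
    tries <- 0
    while (anyNA(out) && tries < 10) {
      redo <- which(is.na(out))
      out[redo] <- draw(length(redo))
      tries <- tries + 1
    }
    if (anyNA(out)) {
      warning(sprintf("%d bootstrap replicate(s) stayed monomorphic and were skipped",
                      sum(is.na(out))))
      out <- out[!is.na(out)]
    }
    out
  })
  alpha <- 1 - conf
  ci <- unname(quantile(dp, c(alpha / 2, 1 - alpha / 2)))
  attr(ci, "replicates") <- dp
  ci
}

#' Four-gamete evidence for historical recombination
#'
#' TRUE iff all four two-locus gametes are present at frequency
#' >= `freq_min` (at least 1% by default).
#'
#' @param counts a [gamete_counts()] object.
#' @param freq_min minimum gamete frequency (inclusive).
#' @return logical.
#' @export
four_gamete_evidence <- function(counts, freq_min = 0.01) {
  if (counts$n_total <= 0) stop("empty gamete counts")
  min(counts$n_AB, counts$n_Ab, counts$n_aB, counts$n_ab) / counts$n_total >= freq_min
}

#' Export pairwise LD for all intrachromosomal adjacent or all pairs
#'
#' Long-format table (chrom, marker_a, marker_b, r2, dprime); CI columns are
#' added when `ci_seed` is given.
#'
#' @param gm a complete [genotype_matrix()].
#' @param map the paired [marker_map()].
#' @param adjacent_only only adjacent pairs (default TRUE; all pairs can be
#'   quadratic in marker count).
#' @param ci_seed optional seed; if given, bootstrap D-prime CI columns are
#'   included.
#' @return data.frame.
#' @export
ld_table <- function(gm, map, adjacent_only = TRUE, ci_seed = NULL) {
  idx <- split(seq_len(nrow(map)), map$chrom)
  rows <- list()
  for (ch in names(idx)) {
    ii <- idx[[ch]]
    prs <- if (adjacent_only) {
      if (length(ii) < 2) next
      cbind(ii[-length(ii)], ii[-1])
    } else t(combn(ii, 2))
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1]; j <- prs[r, 2]
      cnt <- gamete_counts(gm, i, j)
      rec <- data.frame(chrom = ch, marker_a = map$marker[i],
                        marker_b = map$marker[j],
                        r2 = compute_r2(gm, i, j),
                        dprime = compute_dprime(cnt))
      if (!is.null(ci_seed)) {
        ci <- dprime_ci(gm, i, j, seed = derive_seed(ci_seed, i, j))
        rec$ci_lo <- ci[1]; rec$ci_hi <- ci[2]
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}
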