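# Per-window population-genetic metrics. All pairwise window values are means
# of per-SNP values; Tajima's D and Fay & Wu's H use window sums, as the
# classical definitions require.

# per-site nucleotide diversity (unbiased heterozygosity), i alt alleles of n
site_pi <- function(i, n) {
  out <- 2 * i * (n - i) / (n * (n - 1))
  out[n < 2] <- NA_real_
  out
}

# harmonic numbers a1 = sum 1/k, a2 = sum 1/k^2 up to n-1 (vectorized over n)
harmonic <- function(n, power = 1) {
  vapply(n, function(nn) {
    if (is.na(nn) || nn < 2) return(NA_real_)
    sum(1 / (seq_len(nn - 1))^power)
  }, numeric(1))
}

# expand window metadata: used site indices and window grouping factor
window_sites <- function(counts, windows) {
  idx <- unlist(windows$members, use.names = FALSE)
  wid <- rep(windows$window_id, lengths(windows$members))
  list(idx = idx, wid = factor(wid, levels = windows$window_id))
}

wsum <- function(x, wid) {
  out <- rowsum(ifelse(is.na(x), 0, x), wid)
  cnt <- rowsum(as.numeric(!is.na(x)), wid)
  list(sum = as.numeric(out), n = as.numeric(cnt))
}
wmean <- function(x, wid) {
  s <- wsum(x, wid)
  res <- s$sum / s$n
  res[s$n == 0] <- NA_real_
  res
}

#' Window diversity: pi and Watterson's theta
#'
#' Per-SNP nucleotide diversity `2 i (n - i) / (n (n - 1))` averaged over the
#' window, and Watterson's theta per SNP `S / (a1 * size)` with `S` the number
#' of sites polymorphic in the population and `a1` the harmonic number at the
#' window-mean called-allele count.
#'
#' @param counts An [allele_counts()] object.
#' @param windows Windows from [make_windows()].
#' @param population Population label.
#' @return data.frame: `window_id`, `pi`, `theta_w`, plus window sums
#'   (`pi_total`, `S`, `n_mean`) used by the SFS tests.
#' @export
window_diversity <- function(counts, windows, population) {
  ws <- window_sites(counts, windows)
  i <- counts$alt[population, ws$idx]
  n <- counts$called[population, ws$idx]
  pis <- site_pi(i, n)
  poly <- as.numeric(i > 0L & i < n)
  pi_tot <- wsum(pis, ws$wid)
  S <- wsum(poly, ws$wid)$sum
  n_mean <- wmean(n, ws$wid)
  a1 <- harmonic(round(n_mean))
  size <- windows$n_snps
  data.frame(window_id = windows$window_id,
             pi = pi_tot$sum / pi_tot$n,
             theta_w = S / (a1 * size),
             pi_total = pi_tot$sum, S = S, n_mean = n_mean)
}

#' Tajima's D per window
#'
#' `D = (pi_total - S/a1) / sqrt(e1 S + e2 S (S - 1))` with the 1989 variance
#' constants evaluated at the window-mean called-allele count (missing data
#' makes the exact sample size site-specific; the mean-n evaluation is the
#' documented approximation). Windows with no polymorphic site give `NA`.
#'
#' @inheritParams window_diversity
#' @return Numeric vector, one value per window.
#' @export
tajimas_d <- function(counts, windows, population) {
  d <- window_diversity(counts, windows, population)
  n <- round(d$n_mean)
  a1 <- harmonic(n); a2 <- harmonic(n, 2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  S <- d$S
  out <- (d$pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  out[S == 0] <- NA_real_
  out
}

#' Fay and Wu's H per window
#'
#' `H = pi_total - theta_H_total` with `theta_H = 2 i^2 / (n (n - 1))` summed
#' over polarized polymorphic sites, `i` the derived-allele count. Strongly
#' negative H flags an excess of high-frequency derived alleles, the hallmark
#' of a recent sweep with its hitchhiked haplotype near fixation.
#'
#' @inheritParams window_diversity
#' @return Numeric vector, one value per window (`NA` where no polarized
#'   polymorphic site).
#' @export
fay_wu_h <- function(counts, windows, population) {
  if (is.null(counts$derived))
    stop("counts must be polarized first (see polarize())")
  ws <- window_sites(counts, windows)
  i <- counts$derived[population, ws$idx]
  n <- counts$called[population, ws$idx]
  ok <- counts$polarized[ws$idx] & !is.na(i) & i > 0L & i < n
  pis <- ifelse(ok, site_pi(i, n), NA_real_)
  th <- ifelse(ok, 2 * i^2 / (n * (n - 1)), NA_real_)
  h <- wsum(pis - th, ws$wid)
  out <- h$sum
  out[h$n == 0] <- NA_real_
  out
}

# per-SNP Weir-Cockerham theta-hat components from two populations' counts
fst_components <- function(i1, n1, i2, n2) {
  p1 <- i1 / n1; p2 <- i2 / n2
  pbar <- (i1 + i2) / (n1 + n2)
  msp <- n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2          # r - 1 = 1
  msg <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
  nc <- n1 + n2 - (n1^2 + n2^2) / (n1 + n2)
  num <- msp - msg
  den <- msp + (nc - 1) * msg
  fst <- num / den
  fst[den == 0] <- NA_real_
  list(fst = fst, num = num, den = den)
}

#' Weir-Cockerham FST per window
#'
#' Per-SNP Weir-Cockerham theta-hat from the two populations' allele counts;
#' the window value is the mean of per-SNP values (`method = "mean"`, the
#' default) or the ratio of summed variance components
#' (`method = "ratio"`). SNPs at which both populations are monomorphic for
#' the same allele are skipped.
#'
#' @inheritParams window_diversity
#' @param m_pop,nm_pop Population labels of the contrast.
#' @param method `"mean"` or `"ratio"`.
#' @return Numeric vector, one value per window.
#' @export
window_fst <- function(counts, windows, m_pop, nm_pop,
                       method = c("mean", "ratio")) {
  method <- match.arg(method)
  ws <- window_sites(counts, windows)
  fc <- fst_components(counts$alt[m_pop, ws$idx], counts$called[m_pop, ws$idx],
                       counts$alt[nm_pop, ws$idx], counts$called[nm_pop, ws$idx])
  if (method == "mean") {
    wmean(fc$fst, ws$wid)
  } else {
    keep <- !is.na(fc$fst)
    num <- wsum(ifelse(keep, fc$num, NA), ws$wid)$sum
    den <- wsum(ifelse(keep, fc$den, NA), ws$wid)$sum
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
}

#' dXY and dA per window
#'
#' Per-SNP absolute divergence `dXY = p1 (1 - p2) + p2 (1 - p1)` averaged
#' over the window; net divergence `dA = dXY - (pi1 + pi2) / 2` is emitted
#' alongside.
#'
#' @inheritParams window_fst
#' @return data.frame: `window_id`, `dxy`, `d_a`.
#' @export
window_dxy <- function(counts, windows, m_pop, nm_pop) {
  ws <- window_sites(counts, windows)
  p1 <- counts$alt[m_pop, ws$idx] / counts$called[m_pop, ws$idx]
  p2 <- counts$alt[nm_pop, ws$idx] / counts$called[nm_pop, ws$idx]
  dxy <- wmean(p1 * (1 - p2) + p2 * (1 - p1), ws$wid)
  pi1 <- window_diversity(counts, windows, m_pop)$pi
  pi2 <- window_diversity(counts, windows, nm_pop)$pi
  data.frame(window_id = windows$window_id, dxy = dxy,
             d_a = dxy - (pi1 + pi2) / 2)
}

#' Absolute allele-frequency difference per window
#'
#' Window mean of `|p_M - p_NM|` over member SNPs.
#'
#' @inheritParams window_fst
#' @return Numeric vector, one value per window.
#' @export
window_afd <- function(counts, windows, m_pop, nm_pop) {
  ws <- window_sites(counts, windows)
  p1 <- counts$alt[m_pop, ws$idx] / counts$called[m_pop, ws$idx]
  p2 <- counts$alt[nm_pop, ws$idx] / counts$called[nm_pop, ws$idx]
  wmean(abs(p1 - p2), ws$wid)
}

#' Diversity-differentiation (DD) residuals
#'
#' Ordinary least-squares fit of window diversity on window FST across all
#' windows of the contrast; `DD = observed pi - fitted pi`. Strongly negative
#' DD marks windows whose diversity is low relative to their degree of
#' differentiation, the diversity signature of a sweep.
#'
#' @param pi Window diversity values (conventionally of the M population).
#' @param fst Window FST values.
#' @return Numeric vector of residuals (`NA` where either input is missing).
#' @export
dd_residuals <- function(pi, fst) {
  if (length(pi) != length(fst)) stop("pi and fst must align per window")
  ok <- !is.na(pi) & !is.na(fst)
  if (sum(ok) < 10L)
    warning("DD residuals fitted on fewer than 10 windows")
  out <- rep(NA_real_, length(pi))
  if (stats::var(fst[ok]) == 0) {
    warning("no variance in FST; DD degenerates to centred diversity")
    out[ok] <- pi[ok] - mean(pi[ok])
    return(out)
  }
  fit <- stats::lm.fit(cbind(1, fst[ok]), pi[ok])
  out[ok] <- fit$residuals
  out
}

#' Lewontin-Krakauer statistic per window
#'
#' Per-SNP `T = (M - 1) FST_snp / mean(FST)` with `M = 2` populations,
#' averaged per window. With only two populations the kinship-corrected FLK
#' test is not identifiable and the statistic reduces to the classical LK
#' form (documented simplification).
#'
#' @inheritParams window_fst
#' @param fst_bar Genome-wide mean per-SNP FST of the contrast; computed from
#'   all window member SNPs when `NULL`.
#' @return Numeric vector, one value per window.
#' @export
window_flk <- function(counts, windows, m_pop, nm_pop, fst_bar = NULL) {
  ws <- window_sites(counts, windows)
  fst <- fst_components(counts$alt[m_pop, ws$idx],
                        counts$called[m_pop, ws$idx],
                        counts$alt[nm_pop, ws$idx],
                        counts$called[nm_pop, ws$idx])$fst
  if (is.null(fst_bar)) fst_bar <- mean(fst, na.rm = TRUE)
  if (!is.finite(fst_bar) || fst_bar <= 0)
    stop("contrast shows no net differentiation (mean FST <= 0)")
  wmean(fst / fst_bar, ws$wid)
}

# hypergeometric projection weights of derived counts to a fixed sample size
projection_weights <- function(i, n, n_star) {
  W <- matrix(0, nrow = length(i), ncol = n_star + 1L)
  for (j in 0:n_star)
    W[, j + 1L] <- stats::dhyper(j, i, n - i, n_star)
  W
}

#' Two-dimensional SFS composite likelihood ratio per window
#'
#' The genome-wide joint spectrum of derived-allele counts (projected to
#' fixed sample sizes by hypergeometric downsampling, add-one pseudocounts)
#' is the background model; each window's own spectrum is the alternative.
#' `CLR = 2 * sum over window sites of [log G_window - log G_genome]`,
#' clamped at 0. Windows deviating from the genome-wide joint spectrum - the
#' signature expected around sweeps - score high.
#'
#' @inheritParams window_fst
#' @param n_star Projection sample sizes (alleles) for the two populations,
#'   default `c(10, 10)`.
#' @param min_sites Minimum projectable sites per window (default 5).
#' @return Numeric vector, one value per window.
#' @export
sfs2d_clr <- function(counts, windows, m_pop, nm_pop, n_star = c(10L, 10L),
                      min_sites = 5L) {
  if (is.null(counts$derived))
    stop("counts must be polarized first (see polarize())")
  # genome-wide spectrum over all projectable polarized SNPs
  d1 <- counts$derived[m_pop, ]; n1 <- counts$called[m_pop, ]
  d2 <- counts$derived[nm_pop, ]; n2 <- counts$called[nm_pop, ]
  usable <- which(counts$polarized & !is.na(d1) & !is.na(d2) &
                    n1 >= n_star[1] & n2 >= n_star[2] &
                    counts$sites$class == "snp")
  W1 <- projection_weights(d1[usable], n1[usable], n_star[1])
  W2 <- projection_weights(d2[usable], n2[usable], n_star[2])
  G <- crossprod(W1, W2) + 1            # pseudocounted
  logG <- log(G / sum(G))
  rowmap <- rep(NA_integer_, ncol(counts$alt))
  rowmap[usable] <- seq_along(usable)
  out <- rep(NA_real_, nrow(windows))
  for (w in seq_len(nrow(windows))) {
    rows <- rowmap[windows$members[[w]]]
    rows <- rows[!is.na(rows)]
    if (length(rows) < min_sites) next
    Sw <- crossprod(W1[rows, , drop = FALSE], W2[rows, , drop = FALSE])
    logGw <- log((Sw + 1) / (sum(Sw) + length(Sw)))
    out[w] <- max(0, 2 * sum(Sw * (logGw - logG)))
  }
  out
}
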