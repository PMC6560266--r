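# Independent textbook/brute-force oracles. These deliberately use explicit
# loops and the most literal form of each definition, so that they share no
# code path with the package's vectorized implementations.

# mean fraction of differing allele pairs, enumerated over all allele pairs
oracle_pi_site <- function(i, n) {
  if (n < 2) return(NA_real_)
  alleles <- c(rep(1, i), rep(0, n - i))
  diffs <- 0; pairs <- 0
  for (a in 1:(n - 1)) for (b in (a + 1):n) {
    pairs <- pairs + 1
    if (alleles[a] != alleles[b]) diffs <- diffs + 1
  }
  2 * diffs / (2 * pairs)   # per-pair difference probability x 2 draws
}

oracle_window_pi <- function(i_vec, n_vec) {
  mean(mapply(oracle_pi_site, i_vec, n_vec))
}

oracle_theta_w <- function(i_vec, n_vec, size = length(i_vec)) {
  S <- sum(i_vec > 0 & i_vec < n_vec)
  nbar <- round(mean(n_vec))
  a1 <- 0
  for (k in 1:(nbar - 1)) a1 <- a1 + 1 / k
  S / (a1 * size)
}

# Tajima (1989) constants, written out step by step
oracle_tajimas_d <- function(i_vec, n_vec) {
  n <- round(mean(n_vec))
  S <- sum(i_vec > 0 & i_vec < n_vec)
  if (S == 0) return(NA_real_)
  pi_total <- sum(mapply(oracle_pi_site, i_vec, n_vec))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_total - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

oracle_fay_wu_h <- function(d_vec, n_vec) {
  tot <- 0; any_poly <- FALSE
  for (s in seq_along(d_vec)) {
    d <- d_vec[s]; n <- n_vec[s]
    if (d <= 0 || d >= n) next
    any_poly <- TRUE
    tot <- tot + oracle_pi_site(d, n) - 2 * d^2 / (n * (n - 1))
  }
  if (!any_poly) NA_real_ else tot
}

# Weir & Cockerham (1984) theta-hat for allele counts of two populations,
# in the explicit analysis-of-variance form with r populations
oracle_wc_fst_site <- function(i1, n1, i2, n2) {
  r <- 2
  ns <- c(n1, n2); ps <- c(i1 / n1, i2 / n2)
  nbar <- mean(ns)
  nc <- (sum(ns) - sum(ns^2) / sum(ns)) / (r - 1)
  pbar <- sum(ns * ps) / sum(ns)
  msp <- sum(ns * (ps - pbar)^2) / (r - 1)
  msg <- sum(ns * ps * (1 - ps)) / sum(ns - 1)
  den <- msp + (nc - 1) * msg
  if (den == 0) return(NA_real_)
  (msp - msg) / den
}

# dXY by enumerating every between-population pair of allele draws
oracle_dxy_site <- function(i1, n1, i2, n2) {
  a1 <- c(rep(1, i1), rep(0, n1 - i1))
  a2 <- c(rep(1, i2), rep(0, n2 - i2))
  diff <- 0
  for (x in a1) for (y in a2) if (x != y) diff <- diff + 1
  diff / (n1 * n2)
}

# exact upper-tail hypergeometric by enumerating the support
oracle_hyper_upper <- function(k, K, n, N) {
  if (k <= 0) return(1)
  tot <- 0
  for (j in k:min(K, n))
    tot <- tot + choose(K, j) * choose(N - K, n - j) / choose(N, n)
  tot
}

# random window of allele counts for the oracle-equivalence sweeps
random_window <- function(max_snps = 25, max_alleles = 20) {
  m <- sample(2:max_snps, 1)
  n1 <- 2 * sample(2:(max_alleles %/% 2), 1)
  n2 <- 2 * sample(2:(max_alleles %/% 2), 1)
  list(i1 = sample(0:n1, m, replace = TRUE), n1 = rep(n1, m),
       i2 = sample(0:n2, m, replace = TRUE), n2 = rep(n2, m))
}

# wrap one window's counts for two populations into an allele_counts object
counts_from_window <- function(i1, n1, i2, n2, scaffold = "s1") {
  m <- length(i1)
  sites <- data.frame(scaffold = scaffold, pos = seq_len(m) * 10L,
                      ref = "A", alt = "T", class = "snp",
                      stringsAsFactors = FALSE)
  structure(list(alt = rbind(p1 = as.integer(i1), p2 = as.integer(i2)),
                 called = rbind(p1 = as.integer(n1), p2 = as.integer(n2)),
                 pops = c("p1", "p2"), sites = sites),
            class = "allele_counts")
}

one_window <- function(m) {
  w <- data.frame(window_id = 1L, scaffold = "s1", pos_start = 10L,
                  pos_end = m * 10L, n_snps = m)
  w$members <- list(seq_len(m))
  class(w) <- c("snp_windows", "data.frame")
  w
}
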