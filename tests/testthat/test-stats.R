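# Frequency-level metric checks against hand-derived values and invariances.

two_pop_counts <- function(i1, n1, i2, n2) {
  cnt <- counts_from_window(i1, n1, i2, n2)
  polarize(cnt)
}

test_that("per-site diversity and window pi follow the unbiased estimator", {
  cnt <- two_pop_counts(c(1L, 0L, 2L), c(4L, 4L, 4L), c(0L, 0L, 0L),
                        c(4L, 4L, 4L))
  w <- one_window(3L)
  d <- window_diversity(cnt, w, "p1")
  # i=1, n=4 -> 2*1*3/(4*3) = 0.5; i=2 -> 2*2*2/12 = 2/3
  expect_equal(d$pi, mean(c(0.5, 0, 2 / 3)))
  # a monomorphic window has zero diversity under both estimators
  d0 <- window_diversity(cnt, w, "p2")
  expect_equal(d0$pi, 0)
  expect_equal(d0$theta_w, 0)
})

test_that("Tajima's D is zero, negative and positive where theory says", {
  # n = 10: three singletons among 25 sites -> rare-variant excess, D < 0
  i <- c(rep(1L, 3), rep(0L, 22))
  cnt <- two_pop_counts(i, rep(10L, 25), rep(0L, 25), rep(10L, 25))
  d_sing <- tajimas_d(cnt, one_window(25L), "p1")
  expect_lt(d_sing, 0)
  expect_equal(d_sing, oracle_tajimas_d(i, rep(10L, 25)))
  # three mid-frequency SNPs -> D > 0
  i <- c(rep(5L, 3), rep(0L, 22))
  cnt <- two_pop_counts(i, rep(10L, 25), rep(0L, 25), rep(10L, 25))
  d_mid <- tajimas_d(cnt, one_window(25L), "p1")
  expect_gt(d_mid, 0)
  # no polymorphism -> undefined
  cnt0 <- two_pop_counts(rep(0L, 5), rep(10L, 5), rep(0L, 5), rep(10L, 5))
  expect_true(is.na(tajimas_d(cnt0, one_window(5L), "p1")))
})

test_that("Fay and Wu's H tracks the high-frequency derived excess", {
  # all-singleton window: theta_H minimized, H > 0
  cnt <- two_pop_counts(rep(1L, 10), rep(10L, 10), rep(0L, 10), rep(10L, 10))
  expect_gt(fay_wu_h(cnt, one_window(10L), "p1"), 0)
  # single site at i = 9 of n = 10: H = 0.2 - 1.8 = -1.6
  cnt <- two_pop_counts(9L, 10L, 0L, 10L)
  expect_equal(fay_wu_h(cnt, one_window(1L), "p1"), 0.2 - 1.8)
  # unpolarized windows give NA
  cnt$polarized[] <- FALSE
  cnt$derived[] <- NA_integer_
  expect_true(is.na(fay_wu_h(cnt, one_window(1L), "p1")))
})

test_that("Weir-Cockerham FST behaves at fixation and equality", {
  w <- one_window(4L)
  # fixed difference at every site, equal sizes -> per-SNP FST = 1
  cnt <- two_pop_counts(rep(10L, 4), rep(10L, 4), rep(0L, 4), rep(10L, 4))
  expect_equal(window_fst(cnt, w, "p1", "p2"), 1)
  # identical polymorphic frequencies -> window FST <= 0 (unbiased near 0)
  cnt <- two_pop_counts(rep(5L, 4), rep(10L, 4), rep(5L, 4), rep(10L, 4))
  expect_lte(window_fst(cnt, w, "p1", "p2"), 0)
  # hand-evaluated WC value for (6/20, 14/20)
  cnt <- two_pop_counts(6L, 20L, 14L, 20L)
  expect_equal(window_fst(cnt, one_window(1L), "p1", "p2"),
               oracle_wc_fst_site(6, 20, 14, 20))
  # ratio-of-sums option agrees on a single SNP
  expect_equal(window_fst(cnt, one_window(1L), "p1", "p2", method = "ratio"),
               oracle_wc_fst_site(6, 20, 14, 20))
})

test_that("dXY, dA and AFD match their definitions", {
  w <- one_window(2L)
  cnt <- two_pop_counts(c(10L, 5L), c(10L, 10L), c(0L, 5L), c(10L, 10L))
  d <- window_dxy(cnt, w, "p1", "p2")
  expect_equal(d$dxy, mean(c(1, 0.5)))   # fixation -> 1; p=q=0.5 -> 0.5
  expect_equal(d$d_a,
               d$dxy - (window_diversity(cnt, w, "p1")$pi +
                          window_diversity(cnt, w, "p2")$pi) / 2)
  cnt <- two_pop_counts(c(9L, 5L), c(10L, 10L), c(1L, 5L), c(10L, 10L))
  expect_equal(window_afd(cnt, w, "p1", "p2"), mean(c(0.8, 0)))
})

test_that("pairwise metrics are invariant under population swap", {
  set.seed(42)
  for (rep in 1:20) {
    win <- random_window()
    cnt <- two_pop_counts(win$i1, win$n1, win$i2, win$n2)
    m <- length(win$i1)
    w <- one_window(m)
    expect_equal(window_fst(cnt, w, "p1", "p2"),
                 window_fst(cnt, w, "p2", "p1"))
    expect_equal(window_dxy(cnt, w, "p1", "p2")$dxy,
                 window_dxy(cnt, w, "p2", "p1")$dxy)
    expect_equal(window_afd(cnt, w, "p1", "p2"),
                 window_afd(cnt, w, "p2", "p1"))
  }
})

test_that("DD residuals satisfy the least-squares identities", {
  set.seed(1)
  fst <- runif(50, 0, 0.4)
  # perfect collinearity -> all residuals zero
  expect_equal(dd_residuals(2 - 3 * fst, fst), rep(0, 50))
  # generic fit: residuals orthogonal to 1 and to FST
  pi <- 0.2 - 0.3 * fst + rnorm(50, sd = 0.02)
  dd <- dd_residuals(pi, fst)
  expect_equal(sum(dd), 0, tolerance = 1e-10)
  expect_equal(sum(dd * fst), 0, tolerance = 1e-10)
  # a window far below the trend attains the minimum residual
  pi[17] <- pi[17] - 0.15
  expect_equal(which.min(dd_residuals(pi, fst)), 17L)
  # degenerate FST falls back to centred diversity with a warning
  expect_warning(dd0 <- dd_residuals(pi, rep(0.1, 50)), "no variance")
  expect_equal(dd0, pi - mean(pi))
})

test_that("the LK statistic scales per-SNP FST by its genome mean", {
  # fixed differences with mean FST 0.1 -> per-SNP T = (2-1) * 1 / 0.1 = 10
  cnt <- two_pop_counts(rep(10L, 3), rep(10L, 3), rep(0L, 3), rep(10L, 3))
  w <- one_window(3L)
  expect_equal(window_flk(cnt, w, "p1", "p2", fst_bar = 0.1), 10)
  # doubling the genome mean halves T (linearity)
  expect_equal(window_flk(cnt, w, "p1", "p2", fst_bar = 0.2), 5)
  expect_error(window_flk(cnt, w, "p1", "p2", fst_bar = 0),
               "no net differentiation")
  # identical frequencies -> window T at or below 0
  cnt <- two_pop_counts(rep(5L, 3), rep(10L, 3), rep(5L, 3), rep(10L, 3))
  expect_lte(window_flk(cnt, w, "p1", "p2", fst_bar = 0.1), 0)
})

test_that("the 2d-SFS CLR is zero for genome-like windows and positive for
           concentrated ones", {
  set.seed(2)
  m <- 400L
  i1 <- sample(0:10, m, replace = TRUE); i2 <- sample(0:10, m, replace = TRUE)
  cnt <- two_pop_counts(i1, rep(10L, m), i2, rep(10L, m))
  # windows drawn iid from the genome spectrum: CLR small; concentrated
  # window: CLR large
  w <- data.frame(window_id = 1:2, scaffold = "s1",
                  pos_start = c(10L, 260L), pos_end = c(250L, 500L),
                  n_snps = 25L)
  w$members <- list(1:25, 26:50)
  class(w) <- c("snp_windows", "data.frame")
  # make window 2 concentrated in one rare joint cell
  cnt$derived[1, 26:50] <- 10L; cnt$alt[1, 26:50] <- 10L
  cnt$derived[2, 26:50] <- 0L; cnt$alt[2, 26:50] <- 0L
  clr <- sfs2d_clr(cnt, w, "p1", "p2")
  expect_gte(clr[1], 0)
  expect_gt(clr[2], clr[1])
  expect_gt(clr[2], 10)
})

test_that("VarLD scores vanish for identical populations and ignore SNP order", {
  set.seed(3)
  n_ind <- 8L; m <- 25L; W <- 6L
  dos <- matrix(sample(0:2, n_ind * 2 * m * W, replace = TRUE),
                nrow = n_ind * 2)
  sites <- data.frame(scaffold = "s1", pos = seq_len(m * W) * 10L,
                      ref = "A", alt = "T")
  gt <- genotype_table(sites, dos)
  gt$dosages[9:16, ] <- gt$dosages[1:8, ]       # pop2 duplicates pop1
  design <- study_design(
    data.frame(individual = gt$individuals,
               population = rep(c("m", "nm"), each = 8)),
    data.frame(population = c("m", "nm"), site = c("a", "b"),
               soil_class = c("M", "NM"), species = "x", pair = "pair1"))
  cnt <- allele_counts(gt, design)
  w <- make_windows(cnt, seq_len(m * W), size = m)
  raw <- varld_score(gt, design, w, "m", "nm", standardize = FALSE)
  expect_equal(raw, rep(0, W))
  # with distinct populations, permuting SNPs inside a window identically in
  # both populations leaves the raw score unchanged
  gt2 <- genotype_table(sites, dos)
  raw1 <- varld_score(gt2, design, w, "m", "nm", standardize = FALSE)
  perm <- sample(m)
  gt3 <- gt2
  gt3$dosages[, 1:m] <- gt2$dosages[, perm]
  raw2 <- varld_score(gt3, design, w, "m", "nm", standardize = FALSE)
  expect_equal(raw1, raw2)
  # eigenvalues agree with an independent decomposition via svd
  x <- scale(gt2$dosages[1:8, 1:m])
  C <- crossprod(x) / 7; diag(C) <- 1
  sv <- svd(C)$d
  expect_equal(sort(ld_eigen(gt2$dosages[1:8, 1:m]), decreasing = TRUE),
               sort(sv, decreasing = TRUE), tolerance = 1e-8)
})

test_that("the sweep CLR is non-negative and nests the background model", {
  set.seed(4)
  m <- 400L
  cnt <- two_pop_counts(sample(1:9, m, replace = TRUE), rep(10L, m),
                        rep(0L, m), rep(10L, m))
  prof <- sweed_clr(cnt, "p1", grid_step = 20L)
  expect_true(all(prof$clr >= 0))
  # neutral iid spectrum: CLR stays modest everywhere
  expect_lt(max(prof$clr), 30)
  expect_error(sweed_clr(two_pop_counts(1L, 10L, 0L, 10L), "p1"),
               "fewer than")
})

test_that("swept windows dominate the metric tails on planted data", {
  sim <- simulate_dataset(sim_config(
    seed = 11, n_scaffolds = 2, snps_per_scaffold = 5000,
    sweeps = list(list(scaffold = 1, gene = 12, n_genes = 3,
                       pops = "Mias", strength = "strong"))))
  counts <- polarize(allele_counts(sim$gt, sim$design))
  ws <- window_stats(sim$gt, counts, sim$design, 1, include_sweed = TRUE,
                     include_varld = TRUE)
  sw <- sim$truth$sweeps
  mid <- (ws$windows$pos_start + ws$windows$pos_end) / 2
  in_sweep <- ws$windows$scaffold == sw$scaffold & mid >= sw$start &
    mid <= sw$end
  expect_gt(sum(in_sweep), 3)
  st <- ws$stats
  for (m in c("fst", "dxy", "afd", "clr_2dsfs", "clr_sweed_m", "varld")) {
    p <- wilcox.test(st[[m]][in_sweep], st[[m]][!in_sweep],
                     alternative = "greater")$p.value
    expect_lt(p, 0.01)
  }
  for (m in c("tajd_m", "dd", "fwh_m")) {
    p <- wilcox.test(st[[m]][in_sweep], st[[m]][!in_sweep],
                     alternative = "less")$p.value
    expect_lt(p, 0.01)
  }
})
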