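fake_stats <- function(values, metric = "fst") {
  st <- data.frame(window_id = seq_along(values))
  st[[metric]] <- values
  st
}

test_that("outlier calls obey the nearest-rank, ties-included quantile", {
  set.seed(1)
  # 10,000 tie-free windows at q = 0.999 -> exactly 10 calls
  x <- rnorm(10000)
  calls <- empirical_outliers(fake_stats(x), metrics = "fst", q = 0.999)
  expect_equal(nrow(calls), 10L)
  expect_setequal(calls$window_id, order(x, decreasing = TRUE)[1:10])
  # known top values with a tie at the threshold rank -> the tie is included
  y <- c(rep(0, 989), 10:2, 1, 1)     # rank-10 value 1 duplicated
  calls <- empirical_outliers(fake_stats(y), metrics = "fst", q = 0.99)
  expect_equal(nrow(calls), 11L)
  expect_true(all(calls$value >= 1))
  # all-equal metric: everything ties at the threshold, with a warning
  z <- rep(1, 2000)
  expect_warning(
    calls <- empirical_outliers(fake_stats(z), metrics = "fst", q = 0.999),
    "tied")
  expect_equal(nrow(calls), 2000L)
  # lower-tail metrics are called at the opposite end
  calls <- empirical_outliers(fake_stats(x, "dd"), metrics = "dd", q = 0.999)
  expect_setequal(calls$window_id, order(x)[1:10])
  expect_true(all(calls$tail == "lower"))
})

test_that("call counts stay within the tie-bounded band per metric", {
  set.seed(2)
  for (rep_i in 1:5) {
    W <- sample(2000:20000, 1)
    x <- sample(round(rnorm(W), 2))   # rounded -> frequent ties
    calls <- suppressWarnings(
      empirical_outliers(fake_stats(x), metrics = "fst", q = 0.999))
    k <- floor(0.001 * W)
    thr <- sort(x, decreasing = TRUE)[k]
    expect_gte(nrow(calls), k)
    expect_lte(nrow(calls), k + sum(x == thr))
  }
})

test_that("divergence signatures confer candidacy only via dXY, FST and DD", {
  set.seed(3)
  st <- data.frame(window_id = 1:2000, afd = rnorm(2000), dxy = rnorm(2000),
                   fst = rnorm(2000), dd = rnorm(2000), tajd_m = rnorm(2000))
  calls <- divergence_signatures(st)
  expect_setequal(unique(calls$metric[calls$confers_candidacy]),
                  intersect(unique(calls$metric), c("dxy", "fst", "dd")))
  expect_false(any(calls$confers_candidacy[calls$metric %in%
                                             c("afd", "tajd_m")]))
  # tajd and dd are called in the lower tail
  expect_true(all(calls$tail[calls$metric %in% c("dd", "tajd_m")] == "lower"))
  expect_true(all(calls$tail[calls$metric %in% c("afd", "dxy", "fst")] ==
                    "upper"))
})

test_that("gene-window overlap equals brute-force interval intersection", {
  gene_tab <- data.frame(
    gene_id = c("g1", "g2"), scaffold = "s1", strand = "+",
    start = c(100L, 300L), end = c(200L, 400L))
  models <- gene_models(gene_tab,
                        cds = data.frame(gene_id = c("g1", "g2"),
                                         start = c(100L, 300L),
                                         end = c(199L, 399L), phase = 0L))
  w <- data.frame(window_id = 1:2, scaffold = "s1",
                  pos_start = c(150L, 201L), pos_end = c(400L, 299L),
                  n_snps = 25L)
  calls <- data.frame(window_id = 1:2, metric = "fst", value = 1,
                      quantile = 1, tail = "upper")
  ov <- genes_overlapping(calls, w, models)
  # window [150,400] hits both genes; [201,299] hits neither (closed bounds)
  expect_setequal(ov$gene_id[ov$window_id == 1], c("g1", "g2"))
  expect_false(any(ov$window_id == 2))

  # randomized fixture against an all-pairs oracle
  set.seed(4)
  for (rep_i in 1:10) {
    G <- 30; W <- 40
    gs <- sort(sample(1:2000, G)); ge <- gs + sample(20:200, G, TRUE)
    ws_ <- sort(sample(1:2000, W)); we <- ws_ + sample(20:500, W, TRUE)
    models_r <- gene_models(
      data.frame(gene_id = paste0("g", 1:G), scaffold = "s1", strand = "+",
                 start = gs, end = ge),
      cds = data.frame(gene_id = paste0("g", 1:G), start = gs, end = ge,
                       phase = 0L))
    w_r <- data.frame(window_id = 1:W, scaffold = "s1", pos_start = ws_,
                      pos_end = we, n_snps = 25L)
    calls_r <- data.frame(window_id = 1:W, metric = "fst", value = 1,
                          quantile = 1, tail = "upper")
    ov_r <- genes_overlapping(calls_r, w_r, models_r)
    expected <- character(0)
    for (g in 1:G) for (wi in 1:W)
      if (gs[g] <= we[wi] && ge[g] >= ws_[wi])
        expected <- c(expected, paste0("g", g, ":", wi))
    expect_setequal(paste0(ov_r$gene_id, ":", ov_r$window_id), expected)
  }
})

test_that("large-effect screen applies the impact and AFD gates", {
  effects <- data.frame(
    site = 1:4, scaffold = "s1", pos = c(10L, 20L, 30L, 40L),
    gene_id = paste0("g", 1:4),
    effect = c("stop_gained", "frameshift", "missense", "stop_gained"),
    impact = c("HIGH", "HIGH", "MODERATE", "HIGH"))
  sites <- data.frame(scaffold = "s1", pos = c(10L, 20L, 30L, 40L),
                      ref = c("A", "AC", "A", "A"), alt = c("T", "A", "G", "C"),
                      class = c("snp", "indel", "snp", "snp"))
  counts <- structure(list(
    alt = rbind(m = c(20L, 18L, 20L, 10L), nm = c(1L, 1L, 0L, 8L)),
    called = rbind(m = rep(20L, 4), nm = rep(20L, 4)),
    pops = c("m", "nm"), sites = sites), class = "allele_counts")
  hits <- large_effect_screen(effects, counts, "m", "nm")
  # stop at AFD 0.95 in, frameshift at 0.85 out (default 0.9), missense out
  # (impact gate), stop at AFD 0.1 out
  expect_equal(hits$gene_id, "g1")
  expect_equal(hits$afd, 0.95)
  expect_equal(hits$variant_class, "snp")
  # the borderline indel enters when the threshold is relaxed
  hits2 <- large_effect_screen(effects, counts, "m", "nm", afd_min = 0.8)
  expect_setequal(hits2$gene_id, c("g1", "g2"))
  expect_equal(hits2$variant_class[hits2$gene_id == "g2"], "indel")
})

test_that("candidate assembly unions provenance streams deterministically", {
  models <- gene_models(
    data.frame(gene_id = c("gA", "gB", "gC"), scaffold = c("s2", "s1", "s1"),
               strand = "+", start = c(10L, 500L, 20L), end = c(90L, 600L, 80L)),
    cds = data.frame(gene_id = c("gA", "gB", "gC"), start = c(10L, 500L, 20L),
                     end = c(87L, 596L, 79L), phase = 0L))
  scan_genes <- data.frame(gene_id = c("gA", "gB"), window_id = c(1L, 2L),
                           metric = "fst")
  le <- data.frame(gene_id = c("gA", "gC"), site = c(5L, 6L),
                   scaffold = c("s2", "s1"), pos = c(11L, 30L),
                   effect = c("stop_gained", "frameshift"),
                   variant_class = c("snp", "indel"), afd = c(0.95, 0.92))
  cand <- assemble_candidates(scan_genes, NULL, le, models)
  # one record per gene, ordered by (scaffold, start)
  expect_equal(cand$gene_id, c("gC", "gB", "gA"))
  expect_equal(cand$scan_999, c(FALSE, TRUE, TRUE))
  expect_equal(cand$large_effect_snp, c(FALSE, FALSE, TRUE))
  expect_equal(cand$large_effect_indel, c(TRUE, FALSE, FALSE))
  expect_equal(cand$best_afd[cand$gene_id == "gA"], 0.95)
  # empty streams give an empty table
  expect_equal(nrow(assemble_candidates(NULL, NULL, NULL, models)), 0L)
})
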