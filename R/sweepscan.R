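#' Call empirical outlier windows
#'
#' Candidate windows are the empirical tail of each metric's window
#' distribution: the `floor((1 - q) * W)` most extreme windows (upper tail
#' by default; lower tail for metrics whose sweep signature is negative,
#' e.g. DD and Tajima's D), with ties at the threshold all included.
#' Quantiles are computed over non-missing values; the nearest-rank,
#' ties-included definition is deliberate because candidate counts depend on
#' it.
#'
#' @param stats A `window_stats` object or its `stats` data.frame.
#' @param metrics Metric column names to scan (default: the pairwise panel
#'   DD, FST, 2dSFS CLR, dXY, AFD, LK).
#' @param q Empirical quantile (default 0.999: the top 0.1% of windows).
#' @param tails Named character vector overriding the per-metric tail
#'   (`"upper"`/`"lower"`); defaults to the package's sweep-direction table.
#' @return data.frame of outlier calls: `window_id`, `metric`, `value`,
#'   `quantile` (empirical), `tail`.
#' @export
empirical_outliers <- function(stats, metrics = SCAN_METRICS, q = 0.999,
                               tails = METRIC_TAILS) {
  st <- if (inherits(stats, "window_stats")) stats$stats else stats
  W <- nrow(st)
  if (W < 1000L)
    warning("only ", W, " windows; empirical ", q,
            " quantiles are unstable below ~1000 windows")
  calls <- list()
  for (m in metrics) {
    if (!m %in% names(st)) { warning("metric ", m, " absent; skipped"); next }
    x <- st[[m]]
    ok <- !is.na(x)
    if (!any(ok)) { warning("metric ", m, " entirely missing; skipped"); next }
    tail <- if (m %in% names(tails)) tails[[m]] else "upper"
    v <- if (tail == "upper") x else -x
    k <- floor((1 - q) * sum(ok))
    if (k < 1L) next
    thr <- sort(v[ok], decreasing = TRUE)[k]
    hit <- which(ok & v >= thr)
    if (length(hit) == sum(ok) && sum(ok) > k)
      warning("metric ", m, ": all windows tied at the threshold")
    er <- ecdf_rank(v, ok)
    calls[[m]] <- data.frame(window_id = st$window_id[hit], metric = m,
                             value = x[hit], quantile = er[hit], tail = tail,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, calls)
  if (is.null(out))
    out <- data.frame(window_id = integer(0), metric = character(0),
                      value = numeric(0), quantile = numeric(0),
                      tail = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# empirical quantile of each value in the direction already oriented upper
ecdf_rank <- function(v, ok) {
  r <- rep(NA_real_, length(v))
  r[ok] <- rank(v[ok], ties.method = "max") / sum(ok)
  r
}

#' Call divergence signatures (DivergenceScan)
#'
#' The divergence-signature flavour of the outlier scan: 99.5%ile windows
#' (0.5%ile for the lower-tail metrics DD and Tajima's D) over AFD, dXY,
#' FST, DD and Tajima's D. Only dXY, FST and DD confer gene candidacy;
#' AFD and Tajima's D calls are supporting evidence.
#'
#' @inheritParams empirical_outliers
#' @param q Empirical quantile (default 0.995).
#' @return As [empirical_outliers()], with an extra logical column
#'   `confers_candidacy`.
#' @export
divergence_signatures <- function(stats, q = 0.995, metrics = DSCAN_METRICS) {
  calls <- empirical_outliers(stats, metrics = metrics, q = q)
  calls$confers_candidacy <- calls$metric %in% DSCAN_CANDIDACY
  calls
}

#' Map outlier windows to the genes they overlap
#'
#' A gene supports a window call when its span intersects the window's
#' genomic span (closed intervals, same scaffold).
#'
#' @param calls Outlier calls from [empirical_outliers()] or
#'   [divergence_signatures()].
#' @param windows The windows the calls refer to.
#' @param models A [gene_models()] object.
#' @return data.frame: one row per (gene, window, metric) support triple,
#'   with gene coordinates carried along.
#' @export
genes_overlapping <- function(calls, windows, models) {
  if (nrow(calls) == 0L)
    return(data.frame(gene_id = character(0), window_id = integer(0),
                      metric = character(0), stringsAsFactors = FALSE))
  w <- windows[match(calls$window_id, windows$window_id), ]
  wr <- GenomicRanges::GRanges(w$scaffold,
                               IRanges::IRanges(w$pos_start, w$pos_end))
  gr <- GenomicRanges::GRanges(models$genes$scaffold,
                               IRanges::IRanges(models$genes$start,
                                                models$genes$end))
  ov <- GenomicRanges::findOverlaps(wr, gr)
  hit_w <- S4Vectors::queryHits(ov); hit_g <- S4Vectors::subjectHits(ov)
  out <- data.frame(gene_id = models$genes$gene_id[hit_g],
                    scaffold = models$genes$scaffold[hit_g],
                    gene_start = models$genes$start[hit_g],
                    gene_end = models$genes$end[hit_g],
                    window_id = calls$window_id[hit_w],
                    metric = calls$metric[hit_w],
                    value = calls$value[hit_w],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Screen for large-effect variants at divergent frequencies
#'
#' Genome-wide screen complementing the window scans: genes carrying at
#' least one HIGH-impact variant (premature stop, start/stop loss,
#' frameshift, splice disruption) whose absolute allele-frequency difference
#' between the M and NM population exceeds `afd_min` (default 0.9). Such
#' variants can mark selected loss-of-function alleles that window statistics
#' miss. The AFD of every qualifying variant is reported so that borderline
#' hits (the screen's rule is strict inequality) remain visible.
#'
#' @param effects Effect calls from [annotate_effects()].
#' @param counts An [allele_counts()] object.
#' @param m_pop,nm_pop Population labels of the contrast.
#' @param afd_min AFD threshold (exclusive, default 0.9).
#' @return data.frame: `gene_id`, `site`, `scaffold`, `pos`, `effect`,
#'   `variant_class` (`snp`/`indel`), `afd`.
#' @export
large_effect_screen <- function(effects, counts, m_pop, nm_pop,
                                afd_min = 0.9) {
  hi <- effects[effects$impact == "HIGH", , drop = FALSE]
  if (nrow(hi) == 0L)
    return(data.frame(gene_id = character(0), site = integer(0),
                      scaffold = character(0), pos = integer(0),
                      effect = character(0), variant_class = character(0),
                      afd = numeric(0), stringsAsFactors = FALSE))
  f <- allele_freq(counts)
  afd <- abs(f[m_pop, hi$site] - f[nm_pop, hi$site])
  keep <- !is.na(afd) & afd > afd_min
  data.frame(gene_id = hi$gene_id[keep], site = hi$site[keep],
             scaffold = hi$scaffold[keep], pos = hi$pos[keep],
             effect = hi$effect[keep],
             variant_class = counts$sites$class[hi$site[keep]],
             afd = afd[keep], stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble per-contrast candidate genes
#'
#' Unions the evidence streams for one contrast - 99.9%ile scan windows,
#' 99.5%ile divergence signatures (dXY/FST/DD only), and the large-effect
#' screen - into one record per gene with its provenance. Genes whose SNP
#' density exceeds three times the genome median (possible collapsed
#' paralogs) are flagged, not removed.
#'
#' @param scan_genes Gene support table from [genes_overlapping()] on the
#'   99.9%ile calls (or `NULL`).
#' @param dscan_genes As above for [divergence_signatures()] calls; only
#'   rows with candidacy-conferring metrics should be passed (or `NULL`).
#' @param large_effect Output of [large_effect_screen()] (or `NULL`).
#' @param models A [gene_models()] object.
#' @param counts Optional [allele_counts()] for the density flag.
#' @return data.frame of class `candidate_genes`: `gene_id`, `scaffold`,
#'   `start`, `end`, logical provenance columns (`scan_999`,
#'   `divergence_scan_995`, `large_effect_snp`, `large_effect_indel`),
#'   `best_afd`, `n_windows`, `density_flag`; ordered by (scaffold, start).
#' @export
assemble_candidates <- function(scan_genes = NULL, dscan_genes = NULL,
                                large_effect = NULL, models, counts = NULL) {
  ids <- unique(c(scan_genes$gene_id, dscan_genes$gene_id,
                  large_effect$gene_id))
  g <- models$genes[match(ids, models$genes$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = ids, scaffold = g$scaffold, start = g$start,
                    end = g$end, stringsAsFactors = FALSE)
  out$scan_999 <- ids %in% scan_genes$gene_id
  out$divergence_scan_995 <- ids %in% dscan_genes$gene_id
  le_snp <- large_effect$gene_id[large_effect$variant_class == "snp"]
  le_ind <- large_effect$gene_id[large_effect$variant_class == "indel"]
  out$large_effect_snp <- ids %in% le_snp
  out$large_effect_indel <- ids %in% le_ind
  out$best_afd <- vapply(ids, function(id) {
    a <- large_effect$afd[large_effect$gene_id == id]
    if (length(a)) max(a) else NA_real_
  }, numeric(1))
  out$n_windows <- vapply(ids, function(id)
    length(unique(scan_genes$window_id[scan_genes$gene_id == id])) +
      length(unique(dscan_genes$window_id[dscan_genes$gene_id == id])),
    numeric(1))
  out$density_flag <- logical(nrow(out))
  if (!is.null(counts) && nrow(out)) {
    dens <- gene_site_density(models, counts)
    med <- stats::median(dens, na.rm = TRUE)
    out$density_flag <- dens[match(ids, models$genes$gene_id)] > 3 * med
  }
  out <- out[order(out$scaffold, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_genes", "data.frame")
  out
}

# sites per kb of gene span, a coverage-anomaly proxy
gene_site_density <- function(models, counts) {
  by_scaf <- split(seq_len(nrow(counts$sites)), counts$sites$scaffold)
  vapply(seq_len(nrow(models$genes)), function(k) {
    gene <- models$genes[k, ]
    idx <- by_scaf[[gene$scaffold]]
    if (is.null(idx)) return(0)
    n <- length(sites_in_span(counts$sites$pos[idx], gene$start, gene$end))
    n / ((gene$end - gene$start + 1) / 1000)
  }, numeric(1))
}

#' Run the full sweep scan for one contrast
#'
#' End-to-end convenience wrapper: windows, metric panel, 99.9%ile scan
#' outliers, 99.5%ile divergence signatures, large-effect screen, and the
#' assembled candidate table.
#'
#' @inheritParams window_stats
#' @param models A [gene_models()] object.
#' @param effects Optional precomputed [annotate_effects()] table; without
#'   it the large-effect stream is skipped.
#' @param q Scan quantile (default 0.999).
#' @param dscan_q Divergence-signature quantile (default 0.995).
#' @param afd_min Large-effect AFD threshold (default 0.9).
#' @param ... Passed to [window_stats()].
#' @return List of class `sweep_scan`: `stats` (a `window_stats`),
#'   `outliers`, `dscan`, `large_effect`, `candidates`,
#'   `dscan_candidates` (genes from candidacy-conferring divergence
#'   signatures only).
#' @export
scan_contrast <- function(gt, counts, design, contrast, models,
                          effects = NULL, q = 0.999, dscan_q = 0.995,
                          afd_min = 0.9, ...) {
  wstats <- window_stats(gt, counts, design, contrast, ...)
  outl <- empirical_outliers(wstats, q = q)
  dsig <- divergence_signatures(wstats, q = dscan_q)
  scan_genes <- genes_overlapping(outl, wstats$windows, models)
  dscan_genes <- genes_overlapping(
    dsig[dsig$confers_candidacy, , drop = FALSE], wstats$windows, models)
  le <- if (!is.null(effects))
    large_effect_screen(effects, counts, wstats$contrast$m_pop,
                        wstats$contrast$nm_pop, afd_min = afd_min)
  cand <- assemble_candidates(scan_genes, dscan_genes, le, models, counts)
  structure(list(stats = wstats, outliers = outl, dscan = dsig,
                 scan_genes = scan_genes, dscan_genes = dscan_genes,
                 large_effect = le, candidates = cand),
            class = "sweep_scan")
}
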