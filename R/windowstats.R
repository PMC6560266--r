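#' Full per-window metric panel for one M/NM contrast
#'
#' Convenience orchestrator computing the whole window-metric matrix for one
#' contrast: diversity (pi, Watterson's theta), Tajima's D and Fay & Wu's H
#' for both populations, Weir-Cockerham FST, dXY/dA, absolute allele
#' frequency difference, DD residuals, the Lewontin-Krakauer statistic, the
#' 2d-SFS composite likelihood ratio, and optionally the SweepFinder-style
#' CLR and the VarLD contrast (both cost more than the frequency-based
#' metrics and can be switched off for frequency-only scans).
#'
#' @param gt A [genotype_table()] (needed for VarLD dosages).
#' @param counts A polarized [allele_counts()] object.
#' @param design A [study_design()].
#' @param contrast A contrast label from `design$contrasts$contrast`, or a
#'   row index into that table.
#' @param windows Windows from [make_windows()]; built with
#'   [usable_sites()] for this contrast when `NULL`.
#' @param window_size Window size in SNPs when windows are built here.
#' @param include_sweed,include_varld Compute the sweep CLR profile / the
#'   VarLD score (default `TRUE`).
#' @param fst_method Window aggregation for FST, see [window_fst()].
#' @param dd_diversity Diversity series entering the DD regression: `"m"`
#'   (M population, default) or `"mean"` of both populations.
#' @return List of class `window_stats`: `windows`, `stats` (data.frame of
#'   one row per window), `contrast` (the design row), `fst_bar`.
#' @export
window_stats <- function(gt, counts, design, contrast, windows = NULL,
                         window_size = 25L, include_sweed = TRUE,
                         include_varld = TRUE, fst_method = "mean",
                         dd_diversity = c("m", "mean")) {
  dd_diversity <- match.arg(dd_diversity)
  ct <- resolve_contrast(design, contrast)
  if (is.null(counts$derived)) counts <- polarize(counts)
  if (is.null(windows)) {
    us <- usable_sites(counts, ct$m_pop, ct$nm_pop)
    windows <- make_windows(counts, us, size = window_size)
  }
  div_m <- window_diversity(counts, windows, ct$m_pop)
  div_nm <- window_diversity(counts, windows, ct$nm_pop)
  dxy <- window_dxy(counts, windows, ct$m_pop, ct$nm_pop)
  fst <- window_fst(counts, windows, ct$m_pop, ct$nm_pop, method = fst_method)
  pi_dd <- if (dd_diversity == "m") div_m$pi else (div_m$pi + div_nm$pi) / 2

  st <- data.frame(
    window_id = windows$window_id,
    pi_m = div_m$pi, pi_nm = div_nm$pi,
    theta_w_m = div_m$theta_w, theta_w_nm = div_nm$theta_w,
    tajd_m = tajimas_d(counts, windows, ct$m_pop),
    tajd_nm = tajimas_d(counts, windows, ct$nm_pop),
    fwh_m = fay_wu_h(counts, windows, ct$m_pop),
    fwh_nm = fay_wu_h(counts, windows, ct$nm_pop),
    fst = fst, dxy = dxy$dxy, d_a = dxy$d_a,
    afd = window_afd(counts, windows, ct$m_pop, ct$nm_pop),
    dd = dd_residuals(pi_dd, fst),
    flk = window_flk(counts, windows, ct$m_pop, ct$nm_pop),
    clr_2dsfs = sfs2d_clr(counts, windows, ct$m_pop, ct$nm_pop))

  if (include_sweed) {
    n_sites <- nrow(counts$sites)
    st$clr_sweed_m <- sweed_window_max(
      sweed_clr(counts, ct$m_pop), windows, n_sites)
    st$clr_sweed_nm <- sweed_window_max(
      sweed_clr(counts, ct$nm_pop), windows, n_sites)
  }
  if (include_varld)
    st$varld <- varld_score(gt, design, windows, ct$m_pop, ct$nm_pop)

  ws <- window_sites(counts, windows)
  fc <- fst_components(counts$alt[ct$m_pop, ws$idx],
                       counts$called[ct$m_pop, ws$idx],
                       counts$alt[ct$nm_pop, ws$idx],
                       counts$called[ct$nm_pop, ws$idx])
  structure(list(windows = windows, stats = st, contrast = ct,
                 fst_bar = mean(fc$fst, na.rm = TRUE)),
            class = "window_stats")
}

resolve_contrast <- function(design, contrast) {
  cts <- design$contrasts
  if (is.numeric(contrast)) return(cts[contrast, , drop = FALSE])
  row <- cts[cts$contrast == contrast | cts$pair == contrast, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("contrast '", contrast, "' does not identify exactly one design row")
  row
}

# which tail of each metric is sweep-like
METRIC_TAILS <- c(pi_m = "lower", pi_nm = "lower", theta_w_m = "lower",
                  theta_w_nm = "lower", tajd_m = "lower", tajd_nm = "lower",
                  fwh_m = "lower", fwh_nm = "lower", fst = "upper",
                  dxy = "upper", d_a = "upper", afd = "upper", dd = "lower",
                  flk = "upper", clr_2dsfs = "upper", clr_sweed_m = "upper",
                  clr_sweed_nm = "upper", varld = "upper")

# the pairwise metrics entering the 99.9%ile genome scan
SCAN_METRICS <- c("dd", "fst", "clr_2dsfs", "dxy", "afd", "flk")
# the metrics entering the 99.5%ile divergence-signature scan
DSCAN_METRICS <- c("afd", "dxy", "fst", "dd", "tajd_m")
# divergence-signature metrics that confer gene candidacy on their own
DSCAN_CANDIDACY <- c("dxy", "fst", "dd")
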