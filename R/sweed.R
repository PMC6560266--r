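#' SweepFinder-style composite likelihood ratio scan
#'
#' Single-population sweep scan in the spirit of SweepFinder/SweeD. Derived
#' allele counts are projected to a fixed sample size; the genome-wide
#' projected spectrum is the background model. At each grid point (every
#' `grid_step`-th SNP) and for each sweep strength `alpha`, a lineage at
#' distance `d` (kb) escapes the sweep with probability `exp(-alpha * d)`;
#' escaped lineages draw their allele from the background spectrum while
#' swept lineages carry the derived (hitchhiked) allele. The composite
#' likelihood multiplies this distorted spectrum over nearby sites, and
#' `CLR = 2 * (max over alpha of log L - background log L)`, clamped at 0.
#' The alpha grid is log-spaced over 1e-2 to 1e4; as alpha approaches 0 the
#' sweep model collapses onto the background and CLR goes to 0.
#'
#' @param counts A polarized [allele_counts()] object.
#' @param population Population label.
#' @param grid_step Place a grid point at every `grid_step`-th usable SNP
#'   (default 10).
#' @param alpha Sweep-strength grid (per-kb escape rates).
#' @param n_star Projection sample size in alleles (default 10).
#' @param neighborhood Number of SNPs on each side of a grid point entering
#'   the composite likelihood (default 50).
#' @param min_sites Minimum polarized projectable sites per scaffold
#'   (default 25); scaffolds below this are skipped.
#' @return data.frame: `scaffold`, `pos`, `site` (global site index), `clr`.
#' @export
sweed_clr <- function(counts, population, grid_step = 10L,
                      alpha = 10^seq(-2, 4, length.out = 13),
                      n_star = 10L, neighborhood = 50L, min_sites = 25L) {
  if (is.null(counts$derived))
    stop("counts must be polarized first (see polarize())")
  d <- counts$derived[population, ]
  n <- counts$called[population, ]
  usable <- which(counts$polarized & !is.na(d) & n >= n_star &
                    counts$sites$class == "snp")
  if (length(usable) < min_sites)
    stop("fewer than ", min_sites, " polarized projectable sites")
  W <- projection_weights(d[usable], n[usable], n_star)
  phi <- colSums(W) + 1                       # background spectrum
  phi <- phi / sum(phi)
  log_phi <- log(phi)
  l0 <- as.numeric(W %*% log_phi)             # per-site background loglik

  # escaped-lineage derived-count distribution: B[k+1, j+1] = P(j derived
  # among k escaped lineages), mixing over the background frequency classes
  K <- n_star
  B <- matrix(0, K + 1L, K + 1L)
  for (k in 0:K)
    for (j in 0:k)
      B[k + 1L, j + 1L] <- sum(phi * stats::dbinom(j, k, (0:K) / K))
  B[K + 1L, ] <- phi   # fully escaped sites follow the background exactly

  # log-probability table over a discretized escape-probability grid
  pe_grid <- c(0, 10^seq(-6, 0, length.out = 120))
  P_tab <- matrix(0, length(pe_grid), K + 1L)
  for (b in seq_along(pe_grid)) {
    wk <- stats::dbinom(0:K, K, pe_grid[b])
    p <- numeric(K + 1L)
    for (k in 0:K) {
      swept <- K - k                          # swept lineages are derived
      jj <- swept:(swept + k)
      p[jj + 1L] <- p[jj + 1L] + wk[k + 1L] * B[k + 1L, 0:k + 1L]
    }
    P_tab[b, ] <- log(pmax(p, 1e-300))
  }
  pe_bin <- function(pe) pmax(1L, findInterval(pe, pe_grid))

  res <- list()
  for (sc in unique(counts$sites$scaffold[usable])) {
    loc <- usable[counts$sites$scaffold[usable] == sc]
    if (length(loc) < min_sites) {
      warning("scaffold ", sc, ": fewer than ", min_sites,
              " usable sites, profile skipped")
      next
    }
    rows <- match(loc, usable)
    pos <- counts$sites$pos[loc]
    gp <- seq(1L, length(loc), by = grid_step)
    clr <- numeric(length(gp))
    for (gi in seq_along(gp)) {
      g <- gp[gi]
      nb <- max(1L, g - neighborhood):min(length(loc), g + neighborhood)
      dist_kb <- abs(pos[nb] - pos[g]) / 1000
      Wsub <- W[rows[nb], , drop = FALSE]
      ll0 <- sum(l0[rows[nb]])
      ll <- vapply(alpha, function(a) {
        bins <- pe_bin(exp(-a * dist_kb))
        sum(Wsub * P_tab[bins, , drop = FALSE])
      }, numeric(1))
      clr[gi] <- max(0, 2 * (max(ll) - ll0))
    }
    res[[sc]] <- data.frame(scaffold = sc, pos = pos[gp], site = loc[gp],
                            clr = clr, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# fold a grid-point CLR profile into per-window maxima
sweed_window_max <- function(profile, windows, n_sites) {
  map <- window_membership(windows, n_sites)
  out <- rep(NA_real_, nrow(windows))
  if (is.null(profile) || nrow(profile) == 0L) return(out)
  wid <- map[profile$site]
  ok <- !is.na(wid)
  if (!any(ok)) return(out)
  mx <- tapply(profile$clr[ok], wid[ok], max)
  out[match(as.integer(names(mx)), windows$window_id)] <- as.numeric(mx)
  out
}
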