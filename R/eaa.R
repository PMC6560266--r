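#' Estimate the among-population allele-frequency covariance
#'
#' Step one of the two-step environmental association analysis: from
#' putatively neutral SNPs (fourfold-degenerate sites), each SNP's
#' population frequencies are standardized by the across-population mean
#' `eps` and scale `sqrt(eps (1 - eps))`, and the populations x populations
#' covariance of these standardized frequencies is averaged over SNPs. The
#' matrix absorbs shared drift and structure so that the association test
#' does not mistake relatedness for environmental signal. Negative
#' eigenvalues (numerical) are clipped to restore positive
#' semi-definiteness.
#'
#' @param counts An [allele_counts()] object.
#' @param neutral_sites Integer site indices of the neutral SNP set.
#' @param min_sites Hard minimum of usable SNPs (default 50; at least ~500
#'   are recommended).
#' @return List of class `cov_model`: `omega` (P x P), `n_snps`, `pops`.
#' @export
estimate_covariance <- function(counts, neutral_sites, min_sites = 50L) {
  f <- allele_freq(counts)[, neutral_sites, drop = FALSE]
  eps <- colMeans(f)
  ok <- !is.na(eps) & eps > 0 & eps < 1 & colSums(is.na(f)) == 0
  if (sum(ok) < min_sites)
    stop("only ", sum(ok), " usable neutral SNPs (need >= ", min_sites, ")")
  x <- (f[, ok, drop = FALSE] - rep(eps[ok], each = nrow(f))) /
    rep(sqrt(eps[ok] * (1 - eps[ok])), each = nrow(f))
  omega <- tcrossprod(x) / sum(ok)
  eg <- eigen(omega, symmetric = TRUE)
  if (any(eg$values < -1e-8))
    omega <- eg$vectors %*% diag(pmax(eg$values, 0)) %*% t(eg$vectors)
  dimnames(omega) <- list(counts$pops, counts$pops)
  structure(list(omega = omega, n_snps = sum(ok), pops = counts$pops),
            class = "cov_model")
}

#' Bayes factors for environmental association
#'
#' Step two: each SNP's standardized frequency vector `x` is modelled as
#' Gaussian with mean `beta * E` (E the standardized covariate) and
#' covariance Omega. The Bayes factor integrates the likelihood over a
#' uniform prior on the slope, `beta` in `[-beta_max, beta_max]`, by
#' fixed-grid quadrature, against the null `beta = 0`:
#' `BF = mean over the grid of L(beta) / L(0)`. The sign is that of the
#' likelihood-maximizing slope. This Gaussian working model replaces the
#' MCMC of the original two-step tool; it is validated by null calibration
#' (BF tail) and planted-association recovery, not by equivalence to any
#' binary.
#'
#' @param counts An [allele_counts()] object.
#' @param sites Integer site indices to score.
#' @param env data.frame from [read_env()] (columns `population`,
#'   `covariate`, `value`) or a named numeric vector for a single covariate.
#' @param cov_model A `cov_model` from [estimate_covariance()].
#' @param beta_max Half-width of the uniform slope prior (default 1).
#' @param n_grid Quadrature grid points (default 201).
#' @return data.frame: `site`, `covariate`, `bf`, `log10_bf`, `sign`,
#'   `beta_ml`.
#' @export
eaa_bayes_factors <- function(counts, sites, env, cov_model,
                              beta_max = 1, n_grid = 201L) {
  omega <- cov_model$omega
  pops <- cov_model$pops
  if (is.numeric(env))
    env <- data.frame(population = names(env), covariate = "env", value = env)
  stopifnot(all(pops %in% env$population))
  f <- allele_freq(counts)[pops, sites, drop = FALSE]
  eps <- colMeans(f)
  usable <- !is.na(eps) & eps > 0 & eps < 1 & colSums(is.na(f)) == 0
  x <- (f - rep(eps, each = length(pops))) /
    rep(sqrt(eps * (1 - eps)), each = length(pops))
  oi <- solve(omega + diag(1e-10, nrow(omega)))
  beta <- seq(-beta_max, beta_max, length.out = n_grid)

  res <- list()
  for (cv in unique(env$covariate)) {
    ev <- env$value[env$covariate == cv][match(pops,
      env$population[env$covariate == cv])]
    if (stats::sd(ev) == 0)
      stop("covariate '", cv, "' shows no environmental contrast")
    E <- (ev - mean(ev)) / stats::sd(ev)
    c_quad <- as.numeric(t(E) %*% oi %*% E)
    s <- as.numeric(t(E) %*% oi %*% x)              # per-SNP linear term
    # log L(beta) - log L(0) = beta * s - beta^2 * c / 2
    ll <- outer(s, beta) - matrix(rep(beta^2 * c_quad / 2, each = length(s)),
                                  nrow = length(s))
    bf <- rowMeans(exp(ll))
    bml <- beta[max.col(ll, ties.method = "first")]
    bf[!usable] <- NA_real_
    res[[cv]] <- data.frame(site = sites, covariate = cv, bf = bf,
                            log10_bf = log10(bf),
                            sign = ifelse(bml >= 0, "+", "-"),
                            beta_ml = ifelse(usable, bml, NA_real_),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Stringent environmental-association filter chain
#'
#' Retains SNPs that (i) are very strongly associated with a soil covariate
#' (Bayes factor at or above `bf_min`, default 100), (ii) cause a
#' non-synonymous change (missense, stop gained/lost, start lost), and
#' (iii) carry the associated non-reference allele at a higher frequency in
#' both M populations than in their respective NM populations. The chain is
#' monotone in the BF threshold: raising `bf_min` never adds candidates.
#'
#' @param assoc Association table from [eaa_bayes_factors()].
#' @param effects Effect calls from [annotate_effects()].
#' @param counts An [allele_counts()] object.
#' @param design A [study_design()] with two M/NM contrasts (one species).
#' @param bf_min Bayes-factor threshold, inclusive (default 100).
#' @return data.frame of retained SNP x covariate records with `gene_id`,
#'   frequencies in all four populations, and the gates each record passed.
#' @export
stringent_filter <- function(assoc, effects, counts, design, bf_min = 100) {
  cts <- design$contrasts
  if (nrow(cts) != 2L)
    stop("stringent filter expects one species with two M/NM contrasts")
  nonsyn <- c("missense", "stop_gained", "stop_lost", "start_lost")
  eff_ns <- effects[effects$effect %in% nonsyn, c("site", "gene_id", "effect")]
  f <- allele_freq(counts)
  keep <- assoc[!is.na(assoc$bf) & assoc$bf >= bf_min, , drop = FALSE]
  keep <- merge(keep, eff_ns, by = "site")
  if (nrow(keep) == 0L) return(empty_ea())
  m1 <- f[cts$m_pop[1], keep$site]; nm1 <- f[cts$nm_pop[1], keep$site]
  m2 <- f[cts$m_pop[2], keep$site]; nm2 <- f[cts$nm_pop[2], keep$site]
  elev <- !is.na(m1) & !is.na(m2) & m1 > nm1 & m2 > nm2
  out <- data.frame(site = keep$site, covariate = keep$covariate,
                    gene_id = keep$gene_id, effect = keep$effect,
                    bf = keep$bf, sign = keep$sign,
                    freq_m1 = m1, freq_nm1 = nm1,
                    freq_m2 = m2, freq_nm2 = nm2,
                    m_elevated_both = elev, stringsAsFactors = FALSE)
  out <- out[elev, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_ea <- function() {
  data.frame(site = integer(0), covariate = character(0),
             gene_id = character(0), effect = character(0), bf = numeric(0),
             sign = character(0), freq_m1 = numeric(0), freq_nm1 = numeric(0),
             freq_m2 = numeric(0), freq_nm2 = numeric(0),
             m_elevated_both = logical(0), stringsAsFactors = FALSE)
}

#' Union over covariates, intersect over contrasts
#'
#' Per contrast, the union of the covariates' EA gene lists; per species,
#' the intersection of the two contrasts' union lists at the gene level -
#' the species' convergent EA candidates.
#'
#' @param ea_by_contrast Named list (one element per contrast) of data.frames
#'   with columns `gene_id` and `covariate`, e.g. outputs of
#'   [stringent_filter()] restricted to each contrast's tested SNPs.
#' @return List with `union` (named list of per-contrast gene vectors) and
#'   `intersect` (character vector of convergent genes).
#' @export
union_and_intersect <- function(ea_by_contrast) {
  uni <- lapply(ea_by_contrast, function(d) sort(unique(d$gene_id)))
  list(union = uni, intersect = sort(Reduce(intersect, uni)))
}
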