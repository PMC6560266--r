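#' VarLD-style linkage-disequilibrium contrast per window
#'
#' For each window and population, the SNP-by-SNP composite-LD matrix is the
#' genotype (dosage) correlation matrix with sign retained; monomorphic SNPs
#' contribute zero correlation (diagonal kept at 1). The raw score is the
#' summed absolute difference between the two populations' eigenvalue
#' spectra, order-invariant by construction; scores are standardized
#' genome-wide to mean 0 and unit variance across windows. Windows where the
#' local haplotype structure differs between M and NM populations - as after
#' a sweep in one of them - score high.
#'
#' @param gt A [genotype_table()].
#' @param design A [study_design()].
#' @param windows Windows from [make_windows()].
#' @param m_pop,nm_pop Population labels of the contrast.
#' @param standardize Standardize scores across windows (default `TRUE`).
#' @return Numeric vector, one score per window.
#' @export
varld_score <- function(gt, design, windows, m_pop, nm_pop,
                        standardize = TRUE) {
  d1 <- gt$dosages[gt$individuals %in% design_members(design, m_pop), ,
                   drop = FALSE]
  d2 <- gt$dosages[gt$individuals %in% design_members(design, nm_pop), ,
                   drop = FALSE]
  if (nrow(d1) < 2L || nrow(d2) < 2L)
    stop("VarLD needs at least 2 individuals per population")
  raw <- vapply(seq_len(nrow(windows)), function(w) {
    m <- windows$members[[w]]
    sum(abs(ld_eigen(d1[, m, drop = FALSE]) - ld_eigen(d2[, m, drop = FALSE])))
  }, numeric(1))
  if (!standardize) return(raw)
  s <- stats::sd(raw, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(raw - mean(raw, na.rm = TRUE))
  (raw - mean(raw, na.rm = TRUE)) / s
}

# eigenvalues (decreasing) of a window's signed genotype-correlation matrix
ld_eigen <- function(dos) {
  x <- dos
  # mean-impute missing dosages within the population
  for (j in seq_len(ncol(x))) {
    m <- is.na(x[, j])
    if (any(m)) x[m, j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2, stats::sd)
  keep <- is.finite(sds) & sds > 0
  C <- diag(1, ncol(x))
  if (any(keep)) {
    xs <- scale(x[, keep, drop = FALSE])
    C[keep, keep] <- crossprod(xs) / (nrow(x) - 1)
    diag(C) <- 1
  }
  eigen(C, symmetric = TRUE, only.values = TRUE)$values
}
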