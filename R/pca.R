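#' Neutral population-structure PCA
#'
#' Quality-control ordination of individuals on putatively neutral variation:
#' per-individual alt-allele fractions (dosage / 2) at fourfold-degenerate
#' polymorphic SNPs are column-centred and decomposed by PCA. Individuals
#' from genetically distinct populations should separate; the dominant axes
#' should not simply mirror the M/NM soil contrast if the structure is to be
#' trusted as neutral.
#'
#' @param gt A [genotype_table()].
#' @param classes Site classification from [classify_sites()].
#' @param min_sites Minimum number of usable fourfold-degenerate polymorphic
#'   sites (default 2).
#' @return List with `coordinates` (individuals x components),
#'   `var_explained` (fraction per component) and `n_sites`.
#' @export
neutral_structure_pca <- function(gt, classes, min_sites = 2L) {
  stopifnot(inherits(gt, "genotype_table"))
  use <- which(classes$fourfold & gt$sites$class == "snp")
  x <- gt$dosages[, use, drop = FALSE] / 2
  # mean-impute missing genotypes so the decomposition is defined
  for (j in seq_len(ncol(x))) {
    m <- is.na(x[, j])
    if (any(m)) x[m, j] <- mean(x[, j], na.rm = TRUE)
  }
  poly <- apply(x, 2, stats::var) > 0
  poly[is.na(poly)] <- FALSE
  x <- x[, poly, drop = FALSE]
  if (ncol(x) < min_sites || all(!poly))
    stop("no neutral variation: fewer than ", min_sites,
         " polymorphic fourfold-degenerate sites")
  if (nrow(x) < 3L) stop("need at least 3 individuals for structure PCA")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  list(coordinates = pc$x, var_explained = ve, n_sites = ncol(x))
}
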