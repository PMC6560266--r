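#' Genotype table: individuals x sites allele dosages
#'
#' The substrate of all downstream statistics: an ordered site table
#' (scaffold, 1-based position, ref and alt allele) and a matrix of diploid
#' alt-allele dosages (0, 1, 2 or `NA` for missing) with one row per
#' individual and one column per site. Sites with alleles of unequal length
#' are classed as indels; they participate in effect annotation and
#' allele-frequency differences but never in site-frequency-spectrum
#' statistics.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param dosages Integer matrix, individuals x sites, entries in
#'   `c(0, 1, 2, NA)`.
#' @param individuals Character vector of individual identifiers
#'   (default: `rownames(dosages)`).
#' @return An object of class `genotype_table` with elements `sites`
#'   (the site table, plus a `class` column: `"snp"` or `"indel"`),
#'   `dosages` and `individuals`.
#' @export
genotype_table <- function(sites, dosages, individuals = rownames(dosages)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("scaffold", "pos", "ref", "alt") %in% names(sites)))
  dosages <- as.matrix(dosages)
  if (ncol(dosages) != nrow(sites))
    stop("dosage matrix has ", ncol(dosages), " columns for ", nrow(sites),
         " sites")
  if (is.null(individuals))
    individuals <- paste0("ind", seq_len(nrow(dosages)))
  if (length(individuals) != nrow(dosages))
    stop("individual labels do not match dosage rows")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
  sites$pos <- as.integer(sites$pos)
  sites$class <- ifelse(nchar(sites$ref) != nchar(sites$alt), "indel", "snp")

  # enforce (scaffold, pos) order; positions strictly increasing per scaffold
  ord <- order(sites$scaffold, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  dup <- stats::ave(sites$pos, sites$scaffold,
                    FUN = function(p) c(1L, diff(p))) <= 0L
  if (any(dup))
    stop("positions must be strictly increasing within a scaffold")
  rownames(sites) <- NULL
  rownames(dosages) <- individuals
  structure(list(sites = sites, dosages = dosages,
                 individuals = as.character(individuals), ploidy = 2L),
            class = "genotype_table")
}

#' @rdname genotype_table
#' @param x Object to print.
#' @param ... Unused.
#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table:", length(x$individuals), "individuals x",
      nrow(x$sites), "sites (", sum(x$sites$class == "snp"), "SNPs,",
      sum(x$sites$class == "indel"), "indels ) on",
      length(unique(x$sites$scaffold)), "scaffold(s)\n")
  invisible(x)
}

#' Per-population allele counts
#'
#' Collapses genotype dosages to the sufficient statistic of all
#' frequency-based metrics: for every population and site, the alt-allele
#' count and the number of called alleles (2 x non-missing individuals).
#' A population with no called individual at a site gets counts (0, 0) and
#' the site is unusable for that population.
#'
#' @param gt A [genotype_table()].
#' @param design A [study_design()].
#' @return An object of class `allele_counts`: list with `alt` and `called`
#'   (integer matrices, populations x sites), `pops`, and the `sites` table
#'   carried over from `gt`.
#' @export
allele_counts <- function(gt, design) {
  stopifnot(inherits(gt, "genotype_table"), inherits(design, "study_design"))
  missing_ind <- setdiff(design$individuals$individual, gt$individuals)
  if (length(missing_ind))
    stop("design individuals absent from genotypes: ",
         paste(missing_ind, collapse = ", "))
  pops <- design$populations$population
  alt <- called <- matrix(0L, nrow = length(pops), ncol = nrow(gt$sites),
                          dimnames = list(pops, NULL))
  for (p in pops) {
    d <- gt$dosages[gt$individuals %in% design_members(design, p), ,
                    drop = FALSE]
    alt[p, ] <- as.integer(colSums(d, na.rm = TRUE))
    called[p, ] <- as.integer(2L * colSums(!is.na(d)))
  }
  structure(list(alt = alt, called = called, pops = pops, sites = gt$sites),
            class = "allele_counts")
}

#' Polarize allele counts into derived-allele counts
#'
#' Orients each site's alleles into ancestral/derived. By default the
#' reference allele is taken as the ancestral proxy (appropriate when mapping
#' against a diverged heterologous reference), so the derived count equals the
#' alt count. Alternatively an explicit per-site ancestral allele can be
#' supplied (e.g. parsed from an INFO tag); sites whose stated ancestral
#' allele matches neither ref nor alt are left unpolarized and are excluded
#' from derived-allele statistics.
#'
#' @param counts An [allele_counts()] object.
#' @param ancestral `"reference"` (default) or a character vector of ancestral
#'   alleles, one per site.
#' @return `counts` with added elements `derived` (matrix, `NA` where
#'   unpolarized) and `polarized` (logical per site).
#' @export
polarize <- function(counts, ancestral = "reference") {
  stopifnot(inherits(counts, "allele_counts"))
  S <- ncol(counts$alt)
  if (identical(ancestral, "reference")) {
    counts$derived <- counts$alt
    counts$polarized <- rep(TRUE, S)
  } else {
    if (length(ancestral) != S)
      stop("ancestral allele vector must have one entry per site")
    is_ref <- ancestral == counts$sites$ref
    is_alt <- ancestral == counts$sites$alt
    der <- matrix(NA_integer_, nrow = nrow(counts$alt), ncol = S,
                  dimnames = dimnames(counts$alt))
    der[, is_ref] <- counts$alt[, is_ref]
    der[, is_alt] <- counts$called[, is_alt] - counts$alt[, is_alt]
    counts$derived <- der
    counts$polarized <- is_ref | is_alt
  }
  counts
}

# convenience: alt-allele frequency matrix (NA where no called alleles)
allele_freq <- function(counts) {
  f <- counts$alt / counts$called
  f[counts$called == 0L] <- NA_real_
  f
}
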