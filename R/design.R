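#' Study design: individuals, populations, and M/NM contrasts
#'
#' A study design maps sequenced individuals to populations and populations to
#' collection sites, soil classes (metalliferous `M` or non-metalliferous
#' `NM`), species and site pairs. Each site pair contributes one *contrast*:
#' the M population versus the NM population of the same species.
#'
#' @param individuals data.frame with columns `individual`, `population`.
#' @param populations data.frame with columns `population`, `site`,
#'   `soil_class` (`"M"` or `"NM"`), `species`, `pair`.
#' @return An object of class `study_design`: a list with elements
#'   `individuals`, `populations` and `contrasts` (one row per site pair,
#'   columns `contrast`, `pair`, `species`, `m_pop`, `nm_pop`).
#' @export
study_design <- function(individuals, populations) {
  stopifnot(all(c("individual", "population") %in% names(individuals)),
            all(c("population", "site", "soil_class", "species", "pair") %in%
                  names(populations)))
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  if (anyDuplicated(individuals$individual))
    stop("each individual must map to exactly one population")
  if (!all(individuals$population %in% populations$population))
    stop("individuals reference unknown populations: ",
         paste(setdiff(individuals$population, populations$population),
               collapse = ", "))
  if (!all(populations$soil_class %in% c("M", "NM")))
    stop("soil_class must be 'M' or 'NM'")

  contrasts <- do.call(rbind, lapply(
    split(populations, list(populations$pair, populations$species), drop = TRUE),
    function(pp) {
      m <- pp$population[pp$soil_class == "M"]
      nm <- pp$population[pp$soil_class == "NM"]
      if (length(m) != 1L || length(nm) != 1L)
        stop("pair '", pp$pair[1], "' (", pp$species[1], ") must contain ",
             "exactly one M and one NM population")
      data.frame(contrast = paste(pp$site[pp$soil_class == "M"],
                                  pp$site[pp$soil_class == "NM"],
                                  pp$species[1], sep = "-"),
                 pair = pp$pair[1], species = pp$species[1],
                 m_pop = m, nm_pop = nm, stringsAsFactors = FALSE)
    }))
  rownames(contrasts) <- NULL
  structure(list(individuals = individuals, populations = populations,
                 contrasts = contrasts),
            class = "study_design")
}

#' Read a study design table
#'
#' The design TSV has one row per individual with columns `individual`,
#' `population`, `site`, `soil_class`, `species`, `pair`.
#'
#' @param path Path to a tab-separated design file.
#' @return A [study_design()] object.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual", "population", "site", "soil_class", "species", "pair")
  if (!all(need %in% names(d)))
    stop("design file must have columns: ", paste(need, collapse = ", "))
  pops <- unique(d[, c("population", "site", "soil_class", "species", "pair")])
  study_design(d[, c("individual", "population")], pops)
}

#' Read per-population environmental covariates
#'
#' Long-format TSV with columns `population`, `covariate`, `value`, e.g.
#' exchangeable soil Zn and Cd concentrations (mg per kg dry soil).
#'
#' @param path Path to a tab-separated covariate file.
#' @return data.frame with columns `population`, `covariate`, `value`.
#' @export
read_env <- function(path) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("population", "covariate", "value") %in% names(e)))
    stop("environment file must have columns population, covariate, value")
  e$value <- as.numeric(e$value)
  e
}

#' @rdname study_design
#' @param x Object to print.
#' @param ... Unused.
#' @export
print.study_design <- function(x, ...) {
  cat("study_design:", nrow(x$individuals), "individuals,",
      nrow(x$populations), "populations,",
      nrow(x$contrasts), "M/NM contrasts\n")
  print(x$contrasts)
  invisible(x)
}

# individuals belonging to one population, in dosage-matrix order
design_members <- function(design, population) {
  design$individuals$individual[design$individuals$population == population]
}
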