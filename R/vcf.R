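#' Read genotypes from a VCF file
#'
#' Ingests a VCF 4.x file (plain or bgzipped) into a [genotype_table()].
#' Only biallelic records passing FILTER are kept; multiallelic records are
#' skipped with a message. If a design is supplied, every design individual
#' must be present among the VCF samples (hard error otherwise), only design
#' individuals are retained, and sites exceeding the per-population
#' missingness ceiling are dropped.
#'
#' @param path Path to the VCF file.
#' @param design Optional [study_design()] used for sample checking and
#'   per-population missingness filtering.
#' @param max_missing Maximum tolerated fraction of missing genotypes within
#'   any single population (default 0.2). Ignored when `design` is `NULL`.
#' @param pass_only Keep only records whose FILTER is `PASS` or `.`
#'   (default `TRUE`).
#' @return A [genotype_table()].
#' @export
read_vcf <- function(path, design = NULL, max_missing = 0.2,
                     pass_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("no records in VCF: ", path)

  keep <- rep(TRUE, nrow(fix))
  if (pass_only)
    keep <- keep & (is.na(fix$FILTER) | fix$FILTER %in% c("PASS", "."))
  multi <- grepl(",", fix$ALT, fixed = TRUE) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi & keep))
    message(sum(multi & keep), " non-biallelic record(s) skipped")
  keep <- keep & !multi

  gt_chr <- vcfR::extract.gt(v, element = "GT")  # sites x samples
  samples <- colnames(gt_chr)
  if (!is.null(design)) {
    absent <- setdiff(design$individuals$individual, samples)
    if (length(absent))
      stop("design individuals missing from VCF: ",
           paste(absent, collapse = ", "))
    gt_chr <- gt_chr[, design$individuals$individual, drop = FALSE]
    samples <- colnames(gt_chr)
  }

  gt_chr <- gsub("|", "/", gt_chr[keep, , drop = FALSE], fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = ncol(gt_chr), ncol = nrow(gt_chr),
                dimnames = list(samples, NULL))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(code[gt_chr], nrow = nrow(gt_chr)))

  sites <- data.frame(scaffold = fix$CHROM[keep],
                      pos = as.integer(fix$POS[keep]),
                      ref = fix$REF[keep], alt = fix$ALT[keep],
                      stringsAsFactors = FALSE)
  tab <- genotype_table(sites, dos, individuals = samples)

  if (!is.null(design)) {
    miss_ok <- rep(TRUE, nrow(tab$sites))
    for (p in design$populations$population) {
      d <- tab$dosages[tab$individuals %in% design_members(design, p), ,
                       drop = FALSE]
      miss_ok <- miss_ok & (colMeans(is.na(d)) <= max_missing)
    }
    if (!all(miss_ok))
      message(sum(!miss_ok), " site(s) dropped for per-population ",
              "missingness > ", max_missing)
    tab$sites <- tab$sites[miss_ok, , drop = FALSE]
    rownames(tab$sites) <- NULL
    tab$dosages <- tab$dosages[, miss_ok, drop = FALSE]
  }
  tab
}

#' Write a genotype table to a VCF file
#'
#' Emits a minimal VCF 4.2 file (unphased GT field only) that round-trips
#' through [read_vcf()] with dosages preserved exactly.
#'
#' @param gt A [genotype_table()].
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  gts <- matrix("./.", nrow = nrow(gt$dosages), ncol = ncol(gt$dosages))
  gts[gt$dosages == 0L] <- "0/0"
  gts[gt$dosages == 1L] <- "0/1"
  gts[gt$dosages == 2L] <- "1/1"
  body <- paste(gt$sites$scaffold, gt$sites$pos, ".", gt$sites$ref,
                gt$sites$alt, ".", "PASS", ".", "GT",
                apply(gts, 2, paste, collapse = "\t"), sep = "\t")
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gt$individuals), collapse = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}
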