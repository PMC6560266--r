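#' Usable SNPs for a population contrast
#'
#' A SNP is usable for an M/NM contrast when it is biallelic, called in both
#' populations, and polymorphic within the union of the two populations
#' (sites monomorphic in the pair carry no pairwise signal). Set
#' `polymorphic_only = FALSE` to keep all called biallelic SNPs.
#'
#' @param counts An [allele_counts()] object.
#' @param m_pop,nm_pop Population labels of the contrast.
#' @param polymorphic_only Require polymorphism within the pair (default
#'   `TRUE`).
#' @return Integer vector of site indices, in (scaffold, position) order.
#' @export
usable_sites <- function(counts, m_pop, nm_pop, polymorphic_only = TRUE) {
  stopifnot(inherits(counts, "allele_counts"),
            all(c(m_pop, nm_pop) %in% counts$pops))
  snp <- counts$sites$class == "snp"
  i1 <- counts$alt[m_pop, ]; n1 <- counts$called[m_pop, ]
  i2 <- counts$alt[nm_pop, ]; n2 <- counts$called[nm_pop, ]
  ok <- snp & n1 > 0L & n2 > 0L
  if (polymorphic_only) {
    tot <- i1 + i2
    ok <- ok & tot > 0L & tot < (n1 + n2)
  }
  which(ok)
}

#' Partition SNPs into windows of consecutive SNPs
#'
#' Tiles each scaffold's usable SNPs into non-overlapping windows of a fixed
#' number of consecutive SNPs (default 25), the unit of all outlier calling.
#' SNP-count windows keep the per-window information content comparable and
#' avoid the pitfalls of fixed-base-pair windows in regions of uneven SNP
#' density. A trailing remainder of fewer than `size` SNPs per scaffold is
#' dropped.
#'
#' @param counts An [allele_counts()] object (provides site coordinates).
#' @param sites Integer vector of usable site indices, e.g. from
#'   [usable_sites()].
#' @param size Window size in SNPs (default 25).
#' @param step Step between window starts in SNPs; defaults to `size`
#'   (non-overlapping).
#' @return data.frame of class `snp_windows`: `window_id`, `scaffold`,
#'   `pos_start`, `pos_end`, `n_snps`, and a list column `members` of global
#'   site indices. Attribute `dropped` counts remainder SNPs per scaffold.
#' @export
make_windows <- function(counts, sites, size = 25L, step = size) {
  stopifnot(size >= 2L, step >= 1L)
  scaf <- counts$sites$scaffold[sites]
  pos <- counts$sites$pos[sites]
  if (is.unsorted(order(scaf, pos))) {
    o <- order(scaf, pos)
    sites <- sites[o]; scaf <- scaf[o]; pos <- pos[o]
  }
  res <- list(); dropped <- c()
  for (sc in unique(scaf)) {
    idx <- sites[scaf == sc]
    n <- length(idx)
    if (n < size) {
      warning("scaffold ", sc, " has ", n, " usable SNPs (< ", size,
              "): no windows")
      dropped[sc] <- n
      next
    }
    starts <- seq(1L, n - size + 1L, by = step)
    dropped[sc] <- n - (max(starts) + size - 1L)
    res[[sc]] <- data.frame(
      scaffold = sc,
      pos_start = counts$sites$pos[idx[starts]],
      pos_end = counts$sites$pos[idx[starts + size - 1L]],
      n_snps = size, stringsAsFactors = FALSE)
    res[[sc]]$members <- lapply(starts, function(s) idx[s:(s + size - 1L)])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(scaffold = character(0), pos_start = integer(0),
                      pos_end = integer(0), n_snps = integer(0))
  out$window_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("window_id", "scaffold", "pos_start", "pos_end", "n_snps",
                 if ("members" %in% names(out)) "members")]
  attr(out, "dropped") <- dropped
  class(out) <- c("snp_windows", "data.frame")
  out
}

# site index -> window id map (NA for sites outside windows)
window_membership <- function(windows, n_sites) {
  map <- rep(NA_integer_, n_sites)
  for (w in seq_len(nrow(windows)))
    map[windows$members[[w]]] <- windows$window_id[w]
  map
}
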