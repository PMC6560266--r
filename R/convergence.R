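#' Exact hypergeometric overlap test for two gene sets
#'
#' Probability of observing at least the given overlap when two sets of the
#' observed sizes are drawn without replacement from a common gene universe:
#' `p = P(X >= k)` with `X` hypergeometric. The exact tail is used at any
#' universe size relevant to genome annotation.
#'
#' @param set1,set2 Character vectors of gene identifiers.
#' @param universe Character vector of the gene universe; both sets must be
#'   subsets of it.
#' @return List of class `overlap_test`: `K`, `n`, `k`, `N`, `expected`
#'   (`K * n / N`) and `p_value`.
#' @export
hypergeom_overlap <- function(set1, set2, universe) {
  set1 <- unique(set1); set2 <- unique(set2); universe <- unique(universe)
  bad <- c(setdiff(set1, universe), setdiff(set2, universe))
  if (length(bad))
    stop("genes outside universe: ", paste(unique(bad), collapse = ", "))
  K <- length(set1); n <- length(set2); N <- length(universe)
  k <- length(intersect(set1, set2))
  structure(list(K = K, n = n, k = k, N = N, expected = K * n / N,
                 p_value = hyper_upper_tail(k, K, n, N)),
            class = "overlap_test")
}

# P(X >= k) for X ~ Hypergeometric(K successes, N - K failures, n draws)
hyper_upper_tail <- function(k, K, n, N) {
  if (k <= 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' @rdname hypergeom_overlap
#' @param x Object to print.
#' @param ... Unused.
#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf("overlap %d of sets %d x %d in universe %d (expected %.3f): p = %.3g\n",
              x$k, x$K, x$n, x$N, x$expected, x$p_value))
  invisible(x)
}

#' All pairwise overlaps between candidate lists, with Venn counts
#'
#' Tests every pair of candidate gene lists (within-species between-pair,
#' between-species within-pair, and cross comparisons) with
#' [hypergeom_overlap()], and tabulates the Venn regions (exclusive
#' membership patterns) of all lists together.
#'
#' @param candidate_lists Named list of character vectors (e.g. one per
#'   contrast x species).
#' @param universe Gene universe for the tests.
#' @return List with `overlaps` (data.frame: `set1`, `set2`, `K`, `n`, `k`,
#'   `expected`, `p_value`) and `venn` (data.frame: membership `pattern`,
#'   `count`). Venn region counts sum to the size of the union of all lists.
#' @export
convergence_matrix <- function(candidate_lists, universe) {
  stopifnot(length(candidate_lists) >= 2L, !is.null(names(candidate_lists)))
  nm <- names(candidate_lists)
  pairs <- utils::combn(nm, 2, simplify = FALSE)
  overlaps <- do.call(rbind, lapply(pairs, function(p) {
    t <- hypergeom_overlap(candidate_lists[[p[1]]], candidate_lists[[p[2]]],
                           universe)
    data.frame(set1 = p[1], set2 = p[2], K = t$K, n = t$n, k = t$k,
               expected = t$expected, p_value = t$p_value,
               stringsAsFactors = FALSE)
  }))
  all_genes <- sort(unique(unlist(candidate_lists)))
  member <- vapply(candidate_lists, function(s) all_genes %in% s,
                   logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, nm))
  pattern <- apply(member, 1, function(r) paste(nm[r], collapse = "&"))
  venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
  names(venn) <- c("pattern", "count")
  list(overlaps = overlaps, venn = venn)
}

#' Functional over-representation of candidate genes
#'
#' Hypergeometric over-representation test per functional term (e.g. GO
#' biological process, pre-filtered to the desired levels upstream): fold
#' enrichment `(k/n) / (K/N)` and upper-tail p value; a term is reported
#' when both the fold gate (default 3) and the p gate (default 0.05) pass.
#' A Benjamini-Hochberg column is emitted for transparency but does not
#' enter the reported flag.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param gene2term data.frame with columns `gene_id`, `term`.
#' @param universe Character vector of the gene universe.
#' @param fold_min Minimum fold enrichment (default 3).
#' @param p_max Maximum p value (default 0.05).
#' @return data.frame: `term`, `in_universe` (K), `in_candidates` (k),
#'   `fold`, `p_value`, `p_bh`, `reported`.
#' @export
functional_enrichment <- function(candidates, gene2term, universe,
                                  fold_min = 3, p_max = 0.05) {
  stopifnot(all(c("gene_id", "term") %in% names(gene2term)))
  candidates <- unique(candidates); universe <- unique(universe)
  if (length(setdiff(candidates, universe)))
    stop("candidates outside universe: ",
         paste(setdiff(candidates, universe), collapse = ", "))
  g2t <- gene2term[gene2term$gene_id %in% universe, , drop = FALSE]
  skipped <- setdiff(unique(gene2term$term), unique(g2t$term))
  if (length(skipped))
    warning("term(s) with no universe annotation skipped: ",
            paste(skipped, collapse = ", "))
  N <- length(universe); n <- length(candidates)
  res <- do.call(rbind, lapply(split(g2t$gene_id, g2t$term), function(genes) {
    genes <- unique(genes)
    K <- length(genes)
    k <- length(intersect(genes, candidates))
    data.frame(in_universe = K, in_candidates = k,
               fold = (k / n) / (K / N),
               p_value = hyper_upper_tail(k, K, n, N))
  }))
  res$term <- rownames(res)
  rownames(res) <- NULL
  res$p_bh <- stats::p.adjust(res$p_value, method = "BH")
  res$reported <- res$fold >= fold_min & res$p_value < p_max
  res[, c("term", "in_universe", "in_candidates", "fold", "p_value",
          "p_bh", "reported")]
}

#' Screened gene universe of one or more scans
#'
#' The default universe for overlap tests: all genes overlapped by at least
#' one analysis window in every supplied scan (the gene space both contrasts
#' actually screened). Pass the full annotation instead to test against all
#' genes.
#'
#' @param window_list List of window tables (one per contrast).
#' @param models A [gene_models()] object.
#' @return Character vector of gene ids.
#' @export
screened_universe <- function(window_list, models) {
  per_scan <- lapply(window_list, function(w) {
    wr <- GenomicRanges::GRanges(w$scaffold,
                                 IRanges::IRanges(w$pos_start, w$pos_end))
    gr <- GenomicRanges::GRanges(models$genes$scaffold,
                                 IRanges::IRanges(models$genes$start,
                                                  models$genes$end))
    unique(models$genes$gene_id[
      S4Vectors::subjectHits(GenomicRanges::findOverlaps(wr, gr))])
  })
  sort(Reduce(intersect, per_scan))
}
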