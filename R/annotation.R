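#' Gene models
#'
#' Container for protein-coding gene structures: gene spans, exons and CDS
#' segments with phase. Coordinates are 1-based inclusive, as in GFF3.
#' Genes whose concatenated CDS length is not divisible by three (after
#' phase adjustment) are flagged, not rejected: their sites are still classed
#' as coding but receive no degeneracy or effect calls.
#'
#' @param genes data.frame: `gene_id`, `scaffold`, `strand` (`"+"`/`"-"`),
#'   `start`, `end`.
#' @param cds data.frame: `gene_id`, `start`, `end`, `phase` (0/1/2).
#' @param exons Optional data.frame: `gene_id`, `start`, `end`; defaults to
#'   the CDS segments.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, cds, exons = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  cds <- as.data.frame(cds, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "scaffold", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end", "phase") %in% names(cds)))
  if (is.null(exons)) exons <- cds[, c("gene_id", "start", "end")]
  for (g in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == g, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping CDS segments in gene ", g)
    span <- genes[genes$gene_id == g, , drop = FALSE]
    if (nrow(span) == 1L && (min(seg$start) < span$start ||
                             max(seg$end) > span$end))
      stop("CDS outside gene span in gene ", g)
  }
  structure(list(genes = genes, cds = cds,
                 exons = as.data.frame(exons, stringsAsFactors = FALSE)),
            class = "gene_models")
}

#' Read gene models from a GFF3 file
#'
#' Understands the usual gene/mRNA/exon/CDS hierarchy; CDS and exon features
#' are attached to their gene either directly or through the mRNA parent.
#'
#' @param path Path to a GFF3 file.
#' @return A [gene_models()] object.
#' @export
read_gene_models <- function(path) {
  g <- as.data.frame(rtracklayer::readGFF(path))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[1]) else NA_character_, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)
  mrna2gene <- stats::setNames(g$Parent[g$type == "mRNA"],
                               g$ID[g$type == "mRNA"])
  to_gene <- function(parent) {
    out <- ifelse(parent %in% names(mrna2gene), mrna2gene[parent], parent)
    unname(out)
  }
  cds <- g[g$type == "CDS", , drop = FALSE]
  exons <- g[g$type == "exon", , drop = FALSE]
  gene_models(
    genes = data.frame(gene_id = genes$ID, scaffold = as.character(genes$seqid),
                       strand = as.character(genes$strand),
                       start = genes$start, end = genes$end,
                       stringsAsFactors = FALSE),
    cds = data.frame(gene_id = to_gene(cds$Parent), start = cds$start,
                     end = cds$end,
                     phase = ifelse(is.na(cds$phase), 0L, as.integer(cds$phase)),
                     stringsAsFactors = FALSE),
    exons = if (nrow(exons)) data.frame(gene_id = to_gene(exons$Parent),
                                        start = exons$start, end = exons$end,
                                        stringsAsFactors = FALSE) else NULL)
}

#' Read a reference sequence
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by scaffold.
#' @export
read_reference <- function(path) Biostrings::readDNAStringSet(path)

# ---- internal CDS machinery ------------------------------------------------

GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- GENETIC_CODE_TABLE[codon]
  ifelse(is.na(aa), "X", aa)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# reference as per-scaffold character vectors (cached split)
scaffold_chars <- function(reference) {
  if (is.list(reference) && !methods::is(reference, "DNAStringSet"))
    return(reference)
  stats::setNames(lapply(seq_along(reference), function(i)
    strsplit(as.character(reference[[i]]), "")[[1]]), names(reference))
}

# Spliced CDS of one gene: genomic positions in translation order (phase
# trimmed), strand-corrected base sequence, validity flag. `reference` may
# be a DNAStringSet or a pre-split scaffold_chars() list.
cds_map <- function(models, gene_id, reference) {
  seg <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  gene <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(seg) == 0L || nrow(gene) != 1L)
    return(list(valid = FALSE, pos = integer(0), seq = character(0)))
  chars_by_scaf <- scaffold_chars(reference)
  if (!gene$scaffold %in% names(chars_by_scaf))
    stop("scaffold ", gene$scaffold, " absent from reference FASTA")
  minus <- gene$strand == "-"
  seg <- seg[order(seg$start, decreasing = minus), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    p <- seg$start[i]:seg$end[i]
    if (minus) rev(p) else p
  }), use.names = FALSE)
  bases <- chars_by_scaf[[gene$scaffold]][pos]
  if (minus) bases <- unname(COMPLEMENT[bases])
  phase <- seg$phase[1]
  if (phase > 0L) {
    pos <- pos[-seq_len(phase)]
    bases <- bases[-seq_len(phase)]
  }
  list(valid = length(pos) %% 3L == 0L && length(pos) >= 3L,
       pos = pos, seq = bases, minus = minus,
       scaffold = gene$scaffold, strand = gene$strand)
}

# prefixes (first two codon bases) whose third position is fourfold degenerate
fourfold_prefixes <- function() {
  pre <- unique(substr(names(GENETIC_CODE_TABLE), 1, 2))
  pre[vapply(pre, function(p) {
    aa <- GENETIC_CODE_TABLE[paste0(p, c("A", "C", "G", "T"))]
    length(unique(aa)) == 1L
  }, logical(1))]
}

# intron table of one gene from its exons (fall back to CDS segments)
gene_introns <- function(models, gene_id) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) == 0L)
    ex <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  if (nrow(ex) < 2L)
    return(data.frame(start = integer(0), end = integer(0)))
  ex <- ex[order(ex$start), , drop = FALSE]
  data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L)
}

# binary search for site indices whose position falls in [lo, hi]
sites_in_span <- function(pos_sorted, lo, hi) {
  a <- findInterval(lo - 1L, pos_sorted) + 1L
  b <- findInterval(hi, pos_sorted)
  if (b < a) integer(0) else a:b
}

# ---- site classification ---------------------------------------------------

#' Classify variant sites against the annotation
#'
#' Assigns each site a class (`intergenic`, `intron`, `cds`,
#' `splice_region`), records the codon context of coding SNPs, and flags
#' fourfold-degenerate sites: third codon positions whose base never changes
#' the encoded amino acid under the standard genetic code. Fourfold sites are
#' the package's neutral-site proxy (structure PCA, covariance estimation).
#'
#' @param gt A [genotype_table()].
#' @param models A [gene_models()] object.
#' @param reference A `DNAStringSet` as returned by [read_reference()].
#' @return data.frame, one row per site: `class`, `gene_id`, `codon_pos`
#'   (1-3, `NA` outside valid CDS), `fourfold` (logical), `cds_valid`.
#' @export
classify_sites <- function(gt, models, reference) {
  stopifnot(inherits(gt, "genotype_table"), inherits(models, "gene_models"))
  S <- nrow(gt$sites)
  out <- data.frame(class = rep("intergenic", S),
                    gene_id = NA_character_, codon_pos = NA_integer_,
                    fourfold = FALSE, cds_valid = NA,
                    stringsAsFactors = FALSE)
  ff_pre <- fourfold_prefixes()
  by_scaf <- split(seq_len(S), gt$sites$scaffold)
  reference <- scaffold_chars(reference)

  for (k in seq_len(nrow(models$genes))) {
    gene <- models$genes[k, ]
    idx_scaf <- by_scaf[[gene$scaffold]]
    if (is.null(idx_scaf)) next
    pos_scaf <- gt$sites$pos[idx_scaf]
    hit <- idx_scaf[sites_in_span(pos_scaf, gene$start, gene$end)]
    if (!length(hit)) next
    out$class[hit] <- ifelse(out$class[hit] == "cds", out$class[hit], "intron")
    out$gene_id[hit] <- ifelse(is.na(out$gene_id[hit]), gene$gene_id,
                               out$gene_id[hit])

    cm <- cds_map(models, gene$gene_id, reference)
    out$cds_valid[hit] <- cm$valid
    ci <- match(gt$sites$pos[hit], cm$pos)
    in_cds <- !is.na(ci)
    out$class[hit[in_cds]] <- "cds"
    out$gene_id[hit[in_cds]] <- gene$gene_id
    if (cm$valid && any(in_cds)) {
      cidx <- ci[in_cds]
      cpos <- ((cidx - 1L) %% 3L) + 1L
      out$codon_pos[hit[in_cds]] <- cpos
      snp <- gt$sites$class[hit[in_cds]] == "snp"
      third <- cpos == 3L & snp
      if (any(third)) {
        pre <- paste0(cm$seq[cidx[third] - 2L], cm$seq[cidx[third] - 1L])
        out$fourfold[hit[in_cds][third]] <- pre %in% ff_pre
      }
    }

    introns <- gene_introns(models, gene$gene_id)
    if (nrow(introns)) {
      splice_pos <- c(introns$start, introns$start + 1L,
                      introns$end - 1L, introns$end)
      sp <- hit[out$class[hit] == "intron" & gt$sites$pos[hit] %in% splice_pos]
      out$class[sp] <- "splice_region"
    }
  }
  out
}

# ---- effect annotation -----------------------------------------------------

HIGH_EFFECTS <- c("stop_gained", "stop_lost", "start_lost", "frameshift",
                  "splice_donor", "splice_acceptor")

effect_impact <- function(effect) {
  ifelse(effect %in% HIGH_EFFECTS, "HIGH",
         ifelse(effect %in% c("missense", "inframe_indel"), "MODERATE",
                ifelse(effect == "synonymous", "LOW", "MODIFIER")))
}

#' Predict variant effects from the annotation
#'
#' Simplified effect prediction in the spirit of SnpEff: coding SNPs are
#' translated ref-vs-alt (strand aware) into `synonymous`, `missense`,
#' `stop_gained`, `stop_lost` or `start_lost`; intronic SNPs within 2 nt of
#' an exon boundary become `splice_donor`/`splice_acceptor`; CDS indels are
#' `frameshift` when the length difference is not divisible by 3, otherwise
#' `inframe_indel`; an indel spanning an exon boundary is flagged complex and
#' conservatively called `frameshift`. Everything else is `non_coding`.
#' Genes with an untranslatable CDS are skipped (their variants fall through
#' to `non_coding`).
#'
#' @inheritParams classify_sites
#' @return data.frame, one row per (site, overlapping gene): `site` (index
#'   into `gt$sites`), `scaffold`, `pos`, `gene_id`, `effect`, `impact`.
#'   Sites outside genes are omitted.
#' @export
annotate_effects <- function(gt, models, reference) {
  stopifnot(inherits(gt, "genotype_table"), inherits(models, "gene_models"))
  S <- nrow(gt$sites)
  by_scaf <- split(seq_len(S), gt$sites$scaffold)
  reference <- scaffold_chars(reference)
  res <- vector("list", nrow(models$genes))

  for (k in seq_len(nrow(models$genes))) {
    gene <- models$genes[k, ]
    idx_scaf <- by_scaf[[gene$scaffold]]
    if (is.null(idx_scaf)) next
    pos_scaf <- gt$sites$pos[idx_scaf]
    hit <- idx_scaf[sites_in_span(pos_scaf, gene$start, gene$end)]
    if (!length(hit)) next
    cm <- cds_map(models, gene$gene_id, reference)
    introns <- gene_introns(models, gene$gene_id)
    donor_pos <- acceptor_pos <- integer(0)
    if (nrow(introns)) {
      five <- c(introns$start, introns$start + 1L)
      three <- c(introns$end - 1L, introns$end)
      if (gene$strand == "-") { donor_pos <- three; acceptor_pos <- five }
      else { donor_pos <- five; acceptor_pos <- three }
    }

    eff <- character(length(hit))
    for (j in seq_along(hit)) {
      i <- hit[j]
      p <- gt$sites$pos[i]
      ref <- gt$sites$ref[i]; alt <- gt$sites$alt[i]
      if (gt$sites$class[i] == "indel") {
        affected <- p:(p + max(nchar(ref), 1L) - 1L)
        in_cds <- cm$valid && any(affected %in% cm$pos)
        if (!cm$valid) {
          seg <- models$cds[models$cds$gene_id == gene$gene_id, , drop = FALSE]
          in_cds <- any(vapply(seq_len(nrow(seg)), function(s)
            any(affected >= seg$start[s] & affected <= seg$end[s]),
            logical(1)))
        }
        if (in_cds) {
          spans_boundary <- cm$valid && !all(affected %in% cm$pos) &&
            any(affected %in% cm$pos)
          ldiff <- abs(nchar(ref) - nchar(alt))
          eff[j] <- if (spans_boundary || ldiff %% 3L != 0L) "frameshift"
                    else "inframe_indel"
        } else if (p %in% donor_pos) eff[j] <- "splice_donor"
          else if (p %in% acceptor_pos) eff[j] <- "splice_acceptor"
          else eff[j] <- "non_coding"
        next
      }
      ci <- if (cm$valid) match(p, cm$pos) else NA_integer_
      if (!is.na(ci)) {
        cod_n <- (ci - 1L) %/% 3L
        cod <- paste(cm$seq[cod_n * 3L + 1:3], collapse = "")
        off <- ci - cod_n * 3L
        alt_b <- if (cm$minus) unname(COMPLEMENT[alt]) else alt
        alt_cod <- cod
        substr(alt_cod, off, off) <- alt_b
        ref_aa <- translate_codon(cod); alt_aa <- translate_codon(alt_cod)
        eff[j] <- if (cod_n == 0L && ref_aa == "M" && alt_aa != "M")
          "start_lost"
        else if (ref_aa != "*" && alt_aa == "*") "stop_gained"
        else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
        else if (ref_aa == alt_aa) "synonymous"
        else "missense"
      } else if (p %in% donor_pos) eff[j] <- "splice_donor"
        else if (p %in% acceptor_pos) eff[j] <- "splice_acceptor"
        else eff[j] <- "non_coding"
    }
    res[[k]] <- data.frame(site = hit, scaffold = gene$scaffold,
                           pos = gt$sites$pos[hit], gene_id = gene$gene_id,
                           effect = eff, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(site = integer(0), scaffold = character(0),
                      pos = integer(0), gene_id = character(0),
                      effect = character(0), stringsAsFactors = FALSE)
  out$impact <- effect_impact(out$effect)
  rownames(out) <- NULL
  out
}
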