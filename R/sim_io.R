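#' Write a simulated dataset to standard-format files
#'
#' Emits `genotypes.vcf`, `genes.gff3`, `reference.fasta`, `design.tsv`,
#' `env.tsv`, and the truth files `truth_sweeps.bed` (0-based half-open),
#' `truth_ea_snps.tsv` and `truth_large_effects.tsv` into a directory, so a
#' full round trip through the file readers can be exercised.
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(sim$gt, file.path(dir, "genotypes.vcf"))
  d <- merge(sim$design$individuals, sim$design$populations,
             by = "population")
  d <- d[, c("individual", "population", "site", "soil_class", "species",
             "pair")]
  d <- d[order(match(d$individual, sim$design$individuals$individual)), ]
  utils::write.table(d, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$env, file.path(dir, "env.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$reference))
    Biostrings::writeXStringSet(sim$reference,
                                file.path(dir, "reference.fasta"))
  if (!is.null(sim$models))
    write_gff3(sim$models, file.path(dir, "genes.gff3"))
  if (!is.null(sim$truth$sweeps)) {
    sw <- sim$truth$sweeps
    writeLines(paste(sw$scaffold, sw$start - 1L, sw$end, sw$focal_gene,
                     sw$strength, sw$pops, sep = "\t"),
               file.path(dir, "truth_sweeps.bed"))
  }
  if (!is.null(sim$truth$ea_snps))
    utils::write.table(sim$truth$ea_snps,
                       file.path(dir, "truth_ea_snps.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$large_effects))
    utils::write.table(sim$truth$large_effects,
                       file.path(dir, "truth_large_effects.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (k in seq_len(nrow(models$genes))) {
    g <- models$genes[k, ]
    mid <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      paste(g$scaffold, "sim", "gene", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$scaffold, "sim", "mRNA", g$start, g$end, ".", g$strand, ".",
            paste0("ID=", mid, ";Parent=", g$gene_id), sep = "\t"))
    ex <- models$exons[models$exons$gene_id == g$gene_id, , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      lines <- c(lines, paste(g$scaffold, "sim", "exon", ex$start[i],
                              ex$end[i], ".", g$strand, ".",
                              paste0("Parent=", mid), sep = "\t"))
    cd <- models$cds[models$cds$gene_id == g$gene_id, , drop = FALSE]
    for (i in seq_len(nrow(cd)))
      lines <- c(lines, paste(g$scaffold, "sim", "CDS", cd$start[i],
                              cd$end[i], ".", g$strand, cd$phase[i],
                              paste0("Parent=", mid), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' The convergent-adaptation fixture
#'
#' A fixed simulation design exercising the whole pipeline end to end:
#' one strong sweep shared by both M populations (Mias and Klet) spanning
#' seven genes on scaffold 1, one moderate Mias-only sweep on scaffold 2 and
#' one moderate Klet-only sweep on scaffold 3, a planted environmentally
#' associated missense SNP riding the shared swept haplotype in the focal
#' gene, a planted large-effect frameshift indel in the focal gene at AFD
#' 0.86 (a deliberately borderline value against the default 0.9 screen),
#' and a planted stop-gain SNP at AFD 0.95 in an unswept gene. Coding SNPs
#' inside sweep intervals are restricted to synonymous changes so that the
#' set of non-synonymous variants in swept genes - what the stringent
#' association chain can retain - is fully designed.
#'
#' @param seed Integer seed (default 42).
#' @param snps_per_scaffold SNP count per scaffold (default 26000, giving
#'   roughly 4000 scan windows per contrast).
#' @param n_scaffolds Number of scaffolds (default 4).
#' @return A `sim_dataset`; `truth$convergent_genes` names the designed
#'   convergent gene and `truth$ea_snps` the designed chain survivor.
#' @export
make_convergent_fixture <- function(seed = 42L, snps_per_scaffold = 32000L,
                                    n_scaffolds = 4L) {
  spacing <- 15L; gene_spacing <- 2000L
  L <- snps_per_scaffold * spacing + 1500L
  n_genes <- length(seq(200L, L - 2100L, by = gene_spacing))
  focal <- max(5L, as.integer(n_genes * 0.3))
  cfg <- sim_config(
    seed = seed, n_scaffolds = n_scaffolds,
    snps_per_scaffold = snps_per_scaffold, snp_spacing = spacing,
    gene_spacing = gene_spacing,
    sweeps = list(
      list(scaffold = 1, gene = focal, n_genes = 9,
           pops = c("Mias", "Klet"), strength = "strong"),
      list(scaffold = 2, gene = focal, n_genes = 1, pops = "Mias",
           strength = "moderate"),
      list(scaffold = 3, gene = focal, n_genes = 1, pops = "Klet",
           strength = "moderate")),
    ea_snps = list(
      list(scaffold = 1, gene = focal, p_m = c(0.97, 0.95),
           p_nm = c(0.03, 0.05))),
    large_effects = list(
      list(scaffold = 4, gene = max(2L, focal %/% 2L),
           type = "stop_gained", pair = 1, afd = 0.95),
      list(scaffold = 1, gene = focal, type = "frameshift_indel", pair = 2,
           afd = 0.86)),
    sweep_synonymous_only = TRUE)
  simulate_dataset(cfg)
}
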