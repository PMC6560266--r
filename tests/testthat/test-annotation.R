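# Hand-built two-gene fixture with fully known codon content.
#
# chr1 (100 bp):
#   plus-strand gene gA: CDS exon [11,22] + intron [23,34] + CDS exon [35,46]
#     CDS = ATG AAA TGG TTT | GGA CCC TAC TAA
#   minus-strand gene gB: single CDS exon [61,84]
#     CDS (read 84 -> 61) = ATG GGG CAT TGC TGG TTC AAC TAG
hand_fixture <- function(site_df) {
  chars <- rep("A", 100)
  cdsA <- strsplit("ATGAAATGGTTTGGACCCTACTAA", "")[[1]]
  chars[11:22] <- cdsA[1:12]
  chars[35:46] <- cdsA[13:24]
  chars[23:34] <- strsplit("GTAAGTTTTTAG", "")[[1]]
  cdsB <- strsplit("ATGGGGCATTGCTGGTTCAACTAG", "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  chars[84:61] <- unname(comp[cdsB])
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
  models <- gene_models(
    genes = data.frame(gene_id = c("gA", "gB"), scaffold = "chr1",
                       strand = c("+", "-"), start = c(11L, 61L),
                       end = c(46L, 84L)),
    cds = data.frame(gene_id = c("gA", "gA", "gB"),
                     start = c(11L, 35L, 61L), end = c(22L, 46L, 84L),
                     phase = 0L))
  site_df$ref <- vapply(seq_len(nrow(site_df)), function(i)
    if (nchar(site_df$given_ref[i])) site_df$given_ref[i]
    else chars[site_df$pos[i]], character(1))
  sites <- data.frame(scaffold = "chr1", pos = site_df$pos,
                      ref = site_df$ref, alt = site_df$alt)
  gt <- genotype_table(sites, matrix(1L, nrow = 2, ncol = nrow(sites),
                                     dimnames = list(c("i1", "i2"), NULL)))
  list(gt = gt, models = models, reference = ref, chars = chars)
}

hand_sites <- function(pos, alt, given_ref = "") {
  data.frame(pos = pos, alt = alt,
             given_ref = rep_len(given_ref, length(pos)),
             stringsAsFactors = FALSE)
}

test_that("coding SNP effects match manual codon translation on both strands", {
  fx <- hand_fixture(hand_sites(
    pos = c(19L, 22L, 37L, 13L, 43L, 44L, 15L,  # plus-strand gene
            70L, 77L,                           # minus-strand gene
            24L, 33L, 28L),                     # intron of gA
    alt = c("A", "C", "G", "A", "A", "C", "C",
            "T", "C",
            "C", "C", "A")))
  eff <- annotate_effects(fx$gt, fx$models, fx$reference)
  get <- function(pos) eff$effect[eff$pos == pos]
  expect_equal(get(19), "stop_gained")     # TGG -> TGA
  expect_equal(get(22), "synonymous")      # TTT -> TTC
  expect_equal(get(37), "synonymous")      # GGA -> GGG
  expect_equal(get(13), "start_lost")      # ATG -> ATA
  expect_equal(get(43), "stop_gained")     # TAC -> TAA
  expect_equal(get(44), "stop_lost")       # TAA -> CAA
  expect_equal(get(15), "missense")        # AAA -> ACA
  expect_equal(get(70), "stop_gained")     # minus strand TGG -> TGA
  expect_equal(get(77), "missense")        # minus strand CAT -> CGT
  expect_equal(get(24), "splice_donor")    # 2nd intron base, plus strand
  expect_equal(get(33), "splice_acceptor") # 2nd-to-last intron base
  expect_equal(get(28), "non_coding")      # intron interior
  # impact mapping invariant: HIGH iff disruptive effect class
  expect_true(all((eff$impact == "HIGH") ==
                    (eff$effect %in% c("stop_gained", "stop_lost",
                                       "start_lost", "frameshift",
                                       "splice_donor", "splice_acceptor"))))
})

test_that("indel effects follow the length-difference rule", {
  fx <- hand_fixture(data.frame(
    pos = c(14L, 17L, 29L),
    alt = c("A", "A", "T"),
    given_ref = c("AAA", "TGGT", "TTT"),    # 2 bp del, 3 bp del, intronic
    stringsAsFactors = FALSE))
  eff <- annotate_effects(fx$gt, fx$models, fx$reference)
  expect_equal(eff$effect[eff$pos == 14], "frameshift")
  expect_equal(eff$effect[eff$pos == 17], "inframe_indel")
  expect_equal(eff$effect[eff$pos == 29], "non_coding")
  expect_equal(eff$impact[eff$pos == 14], "HIGH")
  expect_equal(eff$impact[eff$pos == 17], "MODERATE")
})

test_that("fourfold degeneracy matches codon-table enumeration for every prefix", {
  # one plus-strand gene carrying all 16 dinucleotide prefixes as codons
  prefixes <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                        paste0)))
  codons <- c("ATG", paste0(prefixes, "A"), "TAA")
  # TAA/TGA prefixes would create internal stops; swap the third base there
  codons[codons == "TAA"] <- "TAC"
  codons[codons == "TGA"] <- "TGC"
  cds <- paste(codons, collapse = "")
  L <- nchar(cds)
  chars <- rep("C", L + 40)
  chars[21:(20 + L)] <- strsplit(cds, "")[[1]]
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
  models <- gene_models(
    genes = data.frame(gene_id = "g", scaffold = "chr1", strand = "+",
                       start = 21L, end = 20L + L),
    cds = data.frame(gene_id = "g", start = 21L, end = 20L + L, phase = 0L))
  third_pos <- 20L + seq(3L, L, by = 3L)
  site_ref <- chars[third_pos]
  alt <- ifelse(site_ref == "A", "G", "A")
  gt <- genotype_table(
    data.frame(scaffold = "chr1", pos = third_pos, ref = site_ref, alt = alt),
    matrix(0L, 1, length(third_pos)))
  cls <- classify_sites(gt, models, ref)
  # oracle: enumerate the genetic code directly
  code <- Biostrings::GENETIC_CODE
  oracle <- vapply(codons, function(cod) {
    pre <- substr(cod, 1, 2)
    length(unique(code[paste0(pre, c("A", "C", "G", "T"))])) == 1L
  }, logical(1))
  expect_equal(cls$fourfold, unname(oracle))
  expect_true(all(cls$class == "cds"))
  expect_true(all(cls$codon_pos == 3L))
})

test_that("invalid CDS lengths flag the gene and suppress degeneracy calls", {
  chars <- rep("A", 60)
  chars[11:30] <- strsplit("ATGAAATGGTTTGGACCCTA", "")[[1]]  # 20 bp: not /3
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(chars, collapse = "")))
  models <- gene_models(
    genes = data.frame(gene_id = "bad", scaffold = "chr1", strand = "+",
                       start = 11L, end = 30L),
    cds = data.frame(gene_id = "bad", start = 11L, end = 30L, phase = 0L))
  gt <- genotype_table(data.frame(scaffold = "chr1", pos = c(16L, 25L),
                                  ref = chars[c(16, 25)], alt = c("G", "G")),
                       matrix(0L, 1, 2))
  cls <- classify_sites(gt, models, ref)
  expect_true(all(cls$class == "cds"))
  expect_false(any(cls$fourfold))
  expect_true(all(cls$cds_valid == FALSE))
  # missing scaffold in the reference is fatal
  models2 <- models
  models2$genes$scaffold <- "chrX"
  models2$cds$gene_id <- "bad"
  gt2 <- genotype_table(data.frame(scaffold = "chrX", pos = 16L, ref = "A",
                                   alt = "G"), matrix(0L, 1, 1))
  expect_error(classify_sites(gt2, models2, ref), "absent from reference")
})

test_that("GFF3 and FASTA round trip through the readers", {
  sim <- simulate_dataset(sim_config(seed = 2, snps_per_scaffold = 300,
                                     n_scaffolds = 1))
  dir <- withr::local_tempdir()
  write_dataset(sim, dir)
  models <- read_gene_models(file.path(dir, "genes.gff3"))
  expect_setequal(models$genes$gene_id, sim$models$genes$gene_id)
  expect_equal(models$cds[order(models$cds$gene_id, models$cds$start),
                          c("start", "end")],
               sim$models$cds[order(sim$models$cds$gene_id,
                                    sim$models$cds$start),
                              c("start", "end")],
               ignore_attr = TRUE)
  ref <- read_reference(file.path(dir, "reference.fasta"))
  expect_equal(as.character(ref), as.character(sim$reference))
  design <- read_design(file.path(dir, "design.tsv"))
  expect_equal(design$contrasts$m_pop, sim$design$contrasts$m_pop)
  env <- read_env(file.path(dir, "env.tsv"))
  expect_equal(env, sim$env, ignore_attr = TRUE)
  # classification of the emitted dataset works without warnings
  expect_silent(classes <- classify_sites(sim$gt, models, ref))
  expect_gt(sum(classes$fourfold), 0)
})
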