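#' Configuration for the synthetic-data generator
#'
#' The generator emulates the sampling design the analysis assumes: one
#' species sampled at two site pairs, each pairing a metalliferous (M) with
#' a non-metalliferous (NM) population (populations Mias/Zapa and Klet/Kowa),
#' eight diploid individuals per population. Neutral allele frequencies
#' follow a hierarchical Balding-Nichols model: a uniform ancestral
#' frequency, Beta-distributed pair-ancestor frequencies at drift
#' `c_between`, and Beta-distributed population frequencies at drift
#' `c_pair` within each pair. Sweeps, environmental associations and
#' large-effect variants are planted on top with full ground truth.
#'
#' @param seed Integer seed; the single source of all randomness.
#' @param species Species label (default `"halleri"`).
#' @param n_ind Diploid individuals per population (default 8).
#' @param n_scaffolds,snps_per_scaffold Genome shape (defaults 4 x 2500).
#' @param snp_spacing Mean distance between SNPs in bp (default 15).
#' @param c_pair,c_between Balding-Nichols drift within pairs (default 0.1)
#'   and between pair ancestors (default 0.2).
#' @param with_annotation Emit gene models and a codon-valid reference
#'   (default `TRUE`); disable for pure frequency-level simulations.
#' @param gene_spacing Distance between gene starts in bp (default 2000).
#' @param sweeps List of sweep specs: `list(scaffold=, gene=, n_genes=1,
#'   pops=c("Mias"), strength="strong")`. `gene` indexes the genes of the
#'   scaffold; the sweep interval spans `n_genes` genes centred on it.
#' @param ea_snps List of planted environmental-association specs:
#'   `list(scaffold=, gene=, p_m=c(Mias=, Klet=), p_nm=c(Zapa=, Kowa=))` -
#'   a missense SNP whose alt-allele frequency follows the M/NM contrast.
#' @param large_effects List of planted HIGH-impact variants:
#'   `list(scaffold=, gene=, type="stop_gained"|"frameshift_indel",
#'   pair=1, afd=0.95)`.
#' @param env Named list of covariates with M and NM values, default
#'   exchangeable soil Zn and Cd with the tenfold M/NM contrast
#'   (`Zn = c(M=300, NM=30)`, `Cd = c(M=12, NM=1.2)`, mg per kg).
#' @param n_indels Additional random neutral indels (default 0).
#' @param sweep_synonymous_only Restrict coding SNPs inside sweep intervals
#'   to synonymous changes (default `FALSE`); used by fixtures that must
#'   pin down exactly which non-synonymous variants exist in swept genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, species = "halleri", n_ind = 8L,
                       n_scaffolds = 4L, snps_per_scaffold = 2500L,
                       snp_spacing = 15L, c_pair = 0.1, c_between = 0.2,
                       with_annotation = TRUE, gene_spacing = 2000L,
                       sweeps = list(), ea_snps = list(),
                       large_effects = list(),
                       env = list(Zn = c(M = 300, NM = 30),
                                  Cd = c(M = 12, NM = 1.2)),
                       n_indels = 0L, sweep_synonymous_only = FALSE) {
  stopifnot(c_pair > 0, c_pair < 1, c_between > 0, c_between < 1,
            n_ind >= 2, snps_per_scaffold >= 2)
  structure(as.list(environment()), class = "sim_config")
}

# sweep strength presets: swept-haplotype frequency Beta(mean, conc), the
# per-site escape probability (fraction of interval sites left unlinked) and
# the post-sweep recovery rate (fraction of linked sites receiving a new
# rare lineage, restoring the singleton excess of a recovering sweep)
SWEEP_STRENGTH <- list(
  strong = list(f_mean = 0.95, f_conc = 60, escape = 0.08, recov = 0.35),
  moderate = list(f_mean = 0.80, f_conc = 40, escape = 0.25, recov = 0.35))

SIM_POPS <- data.frame(
  population = c("Mias", "Zapa", "Klet", "Kowa"),
  site = c("Mias", "Zapa", "Klet", "Kowa"),
  soil_class = c("M", "NM", "M", "NM"),
  pair = c("pair1", "pair1", "pair2", "pair2"),
  stringsAsFactors = FALSE)

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        names(Biostrings::GENETIC_CODE)[
                          Biostrings::GENETIC_CODE == "*"])

# tile two-exon genes over a scaffold and write codon-valid CDS into the
# genome characters; returns gene/cds/exon tables and the updated characters
tile_genes <- function(chars, scaffold, gene_spacing) {
  L <- length(chars)
  starts <- seq(200L, L - 2100L, by = gene_spacing)
  genes <- cds <- exons <- list()
  for (k in seq_along(starts)) {
    s <- starts[k]
    e1 <- c(s, s + 449L)                       # 450 bp
    e2 <- c(s + 750L, s + 1652L)               # 903 bp after a 300 bp intron
    strand <- if (k %% 2L == 0L) "-" else "+"
    codons <- c("ATG", sample(setdiff(SENSE_CODONS, "ATG"), 449L,
                              replace = TRUE), "TAA")
    cds_chars <- strsplit(paste(codons, collapse = ""), "")[[1]]
    if (strand == "+") {
      pos <- c(e1[1]:e1[2], e2[1]:e2[2])
      chars[pos] <- cds_chars
    } else {
      pos <- c(rev(e2[1]:e2[2]), rev(e1[1]:e1[2]))
      chars[pos] <- unname(COMPLEMENT[cds_chars])
    }
    id <- sprintf("gene_s%s_%03d", sub("scaffold_", "", scaffold), k)
    genes[[k]] <- data.frame(gene_id = id, scaffold = scaffold,
                             strand = strand, start = s, end = e2[2],
                             stringsAsFactors = FALSE)
    cds[[k]] <- data.frame(gene_id = id, start = c(e1[1], e2[1]),
                           end = c(e1[2], e2[2]), phase = 0L,
                           stringsAsFactors = FALSE)
    exons[[k]] <- cds[[k]][, c("gene_id", "start", "end")]
  }
  list(chars = chars, genes = do.call(rbind, genes),
       cds = do.call(rbind, cds), exons = do.call(rbind, exons))
}

# pick a CDS site in `cm` where some alt is of the wanted class; returns
# genomic position and genomic alt allele, or NULL
find_coding_site <- function(cm, want = c("missense", "stop_gained",
                                          "synonymous"),
                             exclude_pos = integer(0)) {
  want <- match.arg(want)
  if (!isTRUE(cm$valid)) return(NULL)
  n_codon <- length(cm$pos) %/% 3L
  for (codon_i in sample(2:(n_codon - 1L))) {
    for (off in sample(1:3)) {
      ci <- (codon_i - 1L) * 3L + off
      p <- cm$pos[ci]
      if (p %in% exclude_pos) next
      cod <- paste(cm$seq[(codon_i - 1L) * 3L + 1:3], collapse = "")
      ref_aa <- translate_codon(cod)
      for (b in setdiff(c("A", "C", "G", "T"), cm$seq[ci])) {
        alt_cod <- cod
        substr(alt_cod, off, off) <- b
        aa <- translate_codon(alt_cod)
        hit <- switch(want,
                      missense = aa != ref_aa & aa != "*" & ref_aa != "*",
                      stop_gained = aa == "*" & ref_aa != "*",
                      synonymous = aa == ref_aa)
        if (hit) {
          alt_genomic <- if (cm$minus) unname(COMPLEMENT[b]) else b
          return(list(pos = p, alt = alt_genomic))
        }
      }
    }
  }
  NULL
}

# replace the alt of CDS SNPs inside `interval` by a synonymous change at
# the third position of their codon, dropping sites where impossible
force_synonymous <- function(sites_df, interval, scaffold, models, chars) {
  in_iv <- which(sites_df$scaffold == scaffold &
                   sites_df$pos >= interval[1] & sites_df$pos <= interval[2])
  if (!length(in_iv)) return(sites_df)
  scaf_pos <- sites_df$pos[sites_df$scaffold == scaffold]
  gsel <- models$genes[models$genes$scaffold == scaffold, , drop = FALSE]
  drop <- integer(0)
  for (g in gsel$gene_id) {
    cm <- cds_map(models, g, chars)
    if (!cm$valid) next
    hits <- in_iv[sites_df$pos[in_iv] %in% cm$pos]
    for (i in hits) {
      ci <- match(sites_df$pos[i], cm$pos)
      codon_i <- (ci - 1L) %/% 3L
      ci3 <- codon_i * 3L + 3L
      cod <- paste(cm$seq[codon_i * 3L + 1:3], collapse = "")
      syn_alt <- NULL
      for (b in setdiff(c("A", "C", "G", "T"), cm$seq[ci3])) {
        alt_cod <- cod
        substr(alt_cod, 3L, 3L) <- b
        if (translate_codon(alt_cod) == translate_codon(cod)) {
          syn_alt <- b
          break
        }
      }
      pos3 <- cm$pos[ci3]
      clash <- pos3 != sites_df$pos[i] & pos3 %in% scaf_pos
      if (is.null(syn_alt) || clash) {
        drop <- c(drop, i)
      } else {
        scaf_pos <- c(scaf_pos, pos3)
        sites_df$pos[i] <- pos3
        sites_df$ref[i] <- if (cm$minus) unname(COMPLEMENT[cm$seq[ci3]])
                           else cm$seq[ci3]
        sites_df$alt[i] <- if (cm$minus) unname(COMPLEMENT[syn_alt])
                           else syn_alt
      }
    }
  }
  if (length(drop)) sites_df <- sites_df[-drop, , drop = FALSE]
  sites_df
}

#' Simulate a full synthetic dataset with planted truth
#'
#' Generates reference, annotation, genotypes, design and environment tables
#' according to a [sim_config()], together with a truth object naming every
#' planted sweep interval, causal gene, environmentally associated SNP and
#' large-effect variant. Deterministic under the config seed.
#'
#' Sweeps are simulated at the haplotype level: within the sweep interval a
#' fraction of SNPs (1 - escape probability) is linked to a focal haplotype
#' that carries the derived (alt) allele; in each affected M population the
#' haplotype's frequency is drawn near fixation, individuals carry 0-2
#' copies, and unswept haplotypes sample the pair-ancestor frequency. This
#' produces the full sweep syndrome - lowered diversity, elevated
#' FST/dXY/AFD, negative Tajima's D, an excess of high-frequency derived
#' alleles, and local LD - while leaving unaffected populations neutral.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `gt` ([genotype_table()]), `design`
#'   ([study_design()]), `env` (long covariate table), `models`
#'   ([gene_models()] or `NULL`), `reference` (`DNAStringSet` or `NULL`),
#'   `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  scafs <- paste0("scaffold_", seq_len(config$n_scaffolds))
  L <- config$snps_per_scaffold * config$snp_spacing + 1500L

  chars <- lapply(scafs, function(s)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(chars) <- scafs
  models <- NULL
  if (config$with_annotation) {
    parts <- lapply(scafs, function(s)
      tile_genes(chars[[s]], s, config$gene_spacing))
    names(parts) <- scafs
    for (s in scafs) chars[[s]] <- parts[[s]]$chars
    models <- gene_models(do.call(rbind, lapply(parts, `[[`, "genes")),
                          do.call(rbind, lapply(parts, `[[`, "cds")),
                          do.call(rbind, lapply(parts, `[[`, "exons")))
  }

  # background SNPs
  alt_choices <- t(vapply(c("A", "C", "G", "T"), function(b)
    setdiff(c("A", "C", "G", "T"), b), character(3)))
  sites <- do.call(rbind, lapply(scafs, function(s) {
    pos <- sort(sample(2:(L - 2L), config$snps_per_scaffold))
    ref <- chars[[s]][pos]
    alt <- alt_choices[cbind(match(ref, rownames(alt_choices)),
                             sample.int(3L, length(pos), replace = TRUE))]
    data.frame(scaffold = s, pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }))

  # sweep intervals in genomic coordinates
  sweep_tab <- NULL
  if (length(config$sweeps)) {
    stopifnot(config$with_annotation)
    sweep_tab <- do.call(rbind, lapply(config$sweeps, function(sw) {
      sc <- paste0("scaffold_", sw$scaffold)
      g <- models$genes[models$genes$scaffold == sc, , drop = FALSE]
      if (sw$gene > nrow(g))
        stop("sweep gene index ", sw$gene, " exceeds the ", nrow(g),
             " genes on ", sc)
      w <- if (is.null(sw$n_genes)) 1L else sw$n_genes
      lo <- max(1L, sw$gene - (w - 1L) %/% 2L)
      hi <- min(nrow(g), lo + w - 1L)
      data.frame(scaffold = sc, start = g$start[lo] - 300L,
                 end = g$end[hi] + 300L, pops = paste(sw$pops, collapse = ","),
                 focal_gene = g$gene_id[sw$gene],
                 genes = paste(g$gene_id[lo:hi], collapse = ","),
                 strength = if (is.null(sw$strength)) "strong" else sw$strength,
                 stringsAsFactors = FALSE)
    }))
    if (config$sweep_synonymous_only)
      for (i in seq_len(nrow(sweep_tab)))
        sites <- force_synonymous(sites,
                                  c(sweep_tab$start[i], sweep_tab$end[i]),
                                  sweep_tab$scaffold[i], models, chars)
  }

  # planted environmental-association missense SNPs
  ea_tab <- NULL
  if (length(config$ea_snps)) {
    stopifnot(config$with_annotation)
    ea_tab <- do.call(rbind, lapply(config$ea_snps, function(ea) {
      sc <- paste0("scaffold_", ea$scaffold)
      g <- models$genes[models$genes$scaffold == sc, , drop = FALSE]
      id <- g$gene_id[ea$gene]
      cm <- cds_map(models, id, chars)
      hit <- find_coding_site(cm, "missense", exclude_pos = sites$pos)
      if (is.null(hit)) stop("no missense site available in ", id)
      data.frame(scaffold = sc, pos = hit$pos,
                 ref = chars[[sc]][hit$pos], alt = hit$alt, gene_id = id,
                 p_mias = ea$p_m[1], p_klet = ea$p_m[2],
                 p_zapa = ea$p_nm[1], p_kowa = ea$p_nm[2],
                 stringsAsFactors = FALSE)
    }))
  }

  # planted large-effect variants
  le_tab <- NULL
  if (length(config$large_effects)) {
    stopifnot(config$with_annotation)
    le_tab <- do.call(rbind, lapply(config$large_effects, function(le) {
      sc <- paste0("scaffold_", le$scaffold)
      g <- models$genes[models$genes$scaffold == sc, , drop = FALSE]
      id <- g$gene_id[le$gene]
      cm <- cds_map(models, id, chars)
      if (le$type == "stop_gained") {
        hit <- find_coding_site(cm, "stop_gained", exclude_pos = sites$pos)
        if (is.null(hit)) stop("no stop-gain site available in ", id)
        ref <- chars[[sc]][hit$pos]; alt <- hit$alt; pos <- hit$pos
      } else {                      # frameshift 1-bp deletion inside an exon
        seg <- models$cds[models$cds$gene_id == id, ][1, ]
        pos <- seg$start + 30L
        while (pos %in% sites$pos || (pos + 1L) %in% sites$pos) pos <- pos + 3L
        ref <- paste0(chars[[sc]][pos], chars[[sc]][pos + 1L])
        alt <- chars[[sc]][pos]
      }
      data.frame(scaffold = sc, pos = pos, ref = ref, alt = alt, gene_id = id,
                 type = le$type, pair = le$pair, afd = le$afd,
                 stringsAsFactors = FALSE)
    }))
  }

  # merge planted sites (they displace colliding background SNPs)
  planted <- rbind(
    if (!is.null(ea_tab)) ea_tab[, c("scaffold", "pos", "ref", "alt")],
    if (!is.null(le_tab)) le_tab[, c("scaffold", "pos", "ref", "alt")])
  if (!is.null(planted)) {
    key <- paste(sites$scaffold, sites$pos)
    sites <- sites[!key %in% paste(planted$scaffold, planted$pos), ,
                   drop = FALSE]
    sites <- rbind(sites, planted)
  }
  if (config$n_indels > 0L) {
    ind <- do.call(rbind, lapply(seq_len(config$n_indels), function(i) {
      sc <- sample(scafs, 1L)
      pos <- sample(2:(L - 3L), 1L)
      while (pos %in% sites$pos[sites$scaffold == sc] ||
             (pos + 1L) %in% sites$pos[sites$scaffold == sc])
        pos <- sample(2:(L - 3L), 1L)
      data.frame(scaffold = sc, pos = pos,
                 ref = paste0(chars[[sc]][pos], chars[[sc]][pos + 1L]),
                 alt = chars[[sc]][pos], stringsAsFactors = FALSE)
    }))
    sites <- rbind(sites, ind)
  }
  o <- order(sites$scaffold, sites$pos)
  sites <- sites[o, , drop = FALSE]
  rownames(sites) <- NULL
  S <- nrow(sites)

  # hierarchical Balding-Nichols allele frequencies
  bn <- function(p, c) {
    a <- p * (1 - c) / c
    b <- (1 - p) * (1 - c) / c
    pmin(pmax(stats::rbeta(length(p), a, b), 1e-9), 1 - 1e-9)
  }
  p_anc <- stats::runif(S, 0.05, 0.95)
  p_pair <- rbind(pair1 = bn(p_anc, config$c_between),
                  pair2 = bn(p_anc, config$c_between))
  pops <- SIM_POPS
  p_pop <- t(vapply(seq_len(nrow(pops)), function(i)
    bn(p_pair[pops$pair[i], ], config$c_pair), numeric(S)))
  rownames(p_pop) <- pops$population

  # planted frequency overrides
  if (!is.null(ea_tab))
    for (i in seq_len(nrow(ea_tab))) {
      j <- which(sites$scaffold == ea_tab$scaffold[i] &
                   sites$pos == ea_tab$pos[i])
      p_pop[, j] <- c(ea_tab$p_mias[i], ea_tab$p_zapa[i],
                      ea_tab$p_klet[i], ea_tab$p_kowa[i])
    }
  if (!is.null(le_tab))
    for (i in seq_len(nrow(le_tab))) {
      j <- which(sites$scaffold == le_tab$scaffold[i] &
                   sites$pos == le_tab$pos[i])
      hi <- (1 + le_tab$afd[i]) / 2; lo <- (1 - le_tab$afd[i]) / 2
      p_pop[, j] <- lo
      m_pop <- pops$population[pops$soil_class == "M" &
                                 pops$pair == paste0("pair", le_tab$pair[i])]
      p_pop[m_pop, j] <- hi
    }

  # genotypes
  n_ind <- config$n_ind
  individuals <- unlist(lapply(pops$population, function(p)
    paste0(p, "_", seq_len(n_ind))))
  dos <- matrix(0L, nrow = length(individuals), ncol = S,
                dimnames = list(individuals, NULL))
  for (i in seq_len(nrow(pops))) {
    rows <- (i - 1L) * n_ind + seq_len(n_ind)
    dos[rows, ] <- matrix(stats::rbinom(n_ind * S, 2L,
                                        rep(p_pop[i, ], each = n_ind)),
                          nrow = n_ind)
  }

  # planted large-effect variants: deterministic dosages so the realized
  # AFD reflects the design rather than 16-allele sampling noise
  fill_dosages <- function(count) {
    d <- integer(n_ind)
    full <- count %/% 2L
    d[seq_len(full)] <- 2L
    if (count %% 2L) d[full + 1L] <- 1L
    d
  }
  if (!is.null(le_tab))
    for (i in seq_len(nrow(le_tab))) {
      j <- which(sites$scaffold == le_tab$scaffold[i] &
                   sites$pos == le_tab$pos[i])
      hi <- round((1 + le_tab$afd[i]) / 2 * 2L * n_ind)
      lo <- round((1 - le_tab$afd[i]) / 2 * 2L * n_ind)
      m_pop <- pops$population[pops$soil_class == "M" &
                                 pops$pair == paste0("pair", le_tab$pair[i])]
      for (pi_row in seq_len(nrow(pops))) {
        rows <- (pi_row - 1L) * n_ind + seq_len(n_ind)
        cnt <- if (pops$population[pi_row] == m_pop) hi else lo
        dos[rows, j] <- fill_dosages(cnt)
      }
    }

  # sweep haplotype overrides
  if (!is.null(sweep_tab)) {
    is_snp <- nchar(sites$ref) == nchar(sites$alt)
    for (i in seq_len(nrow(sweep_tab))) {
      iv <- which(sites$scaffold == sweep_tab$scaffold[i] &
                    sites$pos >= sweep_tab$start[i] &
                    sites$pos <= sweep_tab$end[i] & is_snp)
      par <- SWEEP_STRENGTH[[sweep_tab$strength[i]]]
      # linkage to the swept haplotype decays with distance from the focal
      # gene (recombination escape), to a third of its central value at the
      # interval edge
      fg <- models$genes[models$genes$gene_id == sweep_tab$focal_gene[i], ]
      ctr <- (fg$start + fg$end) / 2
      half <- max(sweep_tab$end[i] - ctr, ctr - sweep_tab$start[i])
      p_link <- (1 - par$escape) *
        exp(-log(3) * abs(sites$pos[iv] - ctr) / half)
      linked <- iv[stats::runif(length(iv)) < p_link]
      # planted EA SNPs inside the interval ride the swept haplotype
      if (!is.null(ea_tab)) {
        ea_idx <- which(sites$scaffold %in% ea_tab$scaffold &
                          paste(sites$scaffold, sites$pos) %in%
                            paste(ea_tab$scaffold, ea_tab$pos))
        linked <- union(linked, intersect(iv, ea_idx))
      }
      if (!length(linked)) next
      for (pp in strsplit(sweep_tab$pops[i], ",")[[1]]) {
        pi_row <- match(pp, pops$population)
        f_hap <- stats::rbeta(1, par$f_mean * par$f_conc,
                              (1 - par$f_mean) * par$f_conc)
        sw_h <- stats::rbinom(n_ind, 2L, f_hap)
        rows <- (pi_row - 1L) * n_ind + seq_len(n_ind)
        p_bg <- p_pair[pops$pair[pi_row], linked]
        esc <- matrix(stats::rbinom(n_ind * length(linked),
                                    rep(2L - sw_h, length(linked)),
                                    rep(p_bg, each = n_ind)),
                      nrow = n_ind)
        dos[rows, linked] <- matrix(sw_h, n_ind, length(linked)) + esc
        # post-sweep recovery: new rare ancestral lineages at linked sites
        # (rare-variant excess: negative Tajima's D, strongly negative H)
        rec <- linked[stats::runif(length(linked)) < par$recov]
        for (s in rec) {
          carrier <- rows[dos[rows, s] >= 1L]
          if (length(carrier)) {
            who <- sample(rep(carrier, 2L), 1L)
            dos[who, s] <- dos[who, s] - 1L
          }
        }
      }
    }
  }

  gt <- genotype_table(sites, dos, individuals = individuals)
  pops$species <- config$species
  design <- study_design(
    data.frame(individual = individuals,
               population = rep(pops$population, each = n_ind),
               stringsAsFactors = FALSE),
    pops)
  env <- do.call(rbind, lapply(names(config$env), function(cv)
    data.frame(population = pops$population, covariate = cv,
               value = unname(config$env[[cv]][pops$soil_class]),
               stringsAsFactors = FALSE)))

  match_site <- function(tab) {
    if (is.null(tab)) return(NULL)
    tab$site <- match(paste(tab$scaffold, tab$pos),
                      paste(gt$sites$scaffold, gt$sites$pos))
    tab
  }
  contrast_sweep_genes <- function(m_pop) {
    if (is.null(sweep_tab)) return(character(0))
    hits <- grepl(m_pop, sweep_tab$pops)
    unique(sweep_tab$focal_gene[hits])
  }
  truth <- list(
    sweeps = sweep_tab,
    sweep_genes = list(pair1 = contrast_sweep_genes("Mias"),
                       pair2 = contrast_sweep_genes("Klet")),
    convergent_genes = intersect(contrast_sweep_genes("Mias"),
                                 contrast_sweep_genes("Klet")),
    ea_snps = match_site(ea_tab),
    large_effects = match_site(le_tab))

  reference <- NULL
  if (config$with_annotation)
    reference <- Biostrings::DNAStringSet(
      stats::setNames(vapply(chars, paste, character(1), collapse = ""),
                      names(chars)))
  structure(list(gt = gt, design = design, env = env, models = models,
                 reference = reference, truth = truth, config = config),
            class = "sim_dataset")
}
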