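---
title: "Methods: windowed sweep scans, environmental association and convergence testing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed sweep scans, environmental association and convergence testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Plant populations that colonize calamine metalliferous (M) soils — soils
carrying toxic levels of zinc and cadmium — repeatedly evolve tolerance from
nearby non-metalliferous (NM) populations. When the same M/NM contrast is
replicated at two site pairs, and in two co-occurring species, genes under
selection in more than one independent contrast are candidates for
*convergent* adaptation. `convergescan` implements the discovery pipeline
for this design: windowed selective-sweep scans per M/NM contrast, a
genome-wide large-effect variant screen, a Bayes-factor environmental
association analysis (EAA) with a stringent filter chain, and exact
hypergeometric tests of candidate-list overlap between contrasts and
species.

The package operates downstream of variant calling: its inputs are a VCF of
biallelic SNPs and short indels, a GFF3 annotation, a reference FASTA, a
design table (individual, population, site, soil class, species, site
pair), and a table of per-population soil covariates (e.g. exchangeable Zn
and Cd in mg per kg).

# Windows and metrics

Each contrast's usable SNPs — biallelic, called in both populations,
polymorphic within the pair — are tiled into non-overlapping windows of 25
consecutive SNPs. SNP-count windows hold the per-window information content
constant where SNP density varies, which fixed-base-pair windows do not.
The window is the unit of outlier calling; the trailing remainder of a
scaffold is dropped.

Per window the package computes, from per-population allele counts:

* nucleotide diversity $\pi$ (window mean of $2i(n-i)/(n(n-1))$) and
  Watterson's $\theta_W = S/(a_1 \cdot \text{size})$ per population;
* Tajima's $D$, from window-summed $\pi$ and $\theta_W$ with the 1989
  variance constants evaluated at the window-mean called-allele count.
  Missing genotypes make the exact sample size site-specific; evaluating
  the constants at the (rounded) window mean is the documented
  approximation, exact when data are complete;
* Fay & Wu's $H = \pi - \theta_H$, $\theta_H = \sum 2i^2/(n(n-1))$ over
  polarized sites, with the reference allele as the ancestral proxy (the
  reference is a diverged heterologous genome, so the non-reference allele
  is treated as derived; an explicit per-site ancestral allele can be
  supplied instead);
* Weir–Cockerham $F_{ST}$ (per-SNP estimator from the two populations'
  allele counts; window value is the mean of per-SNP values, with a
  ratio-of-sums variant available);
* absolute divergence $d_{XY} = p_1(1-p_2) + p_2(1-p_1)$ and net divergence
  $d_A = d_{XY} - (\pi_1+\pi_2)/2$;
* the absolute allele-frequency difference AFD;
* DD residuals: ordinary least squares of window diversity (of the M
  population by default; configurable to the pair mean) on window
  $F_{ST}$; strongly negative residuals mark windows whose diversity is
  low relative to their differentiation;
* the Lewontin–Krakauer statistic $T = (M-1)\,F_{ST}/\bar F_{ST}$ with
  $M = 2$ populations. With two populations the kinship-tree correction of
  the full FLK test is not identifiable, so the statistic deliberately
  reduces to the classical LK form;
* a two-dimensional site-frequency-spectrum composite likelihood ratio:
  derived counts are projected by hypergeometric downsampling to a fixed
  sample size (10, 10), the genome-wide joint spectrum (add-one
  pseudocounts) is the background, and
  $\mathrm{CLR} = 2\sum_{\text{sites}}[\log \hat G_{\text{win}} - \log G]$,
  clamped at zero;
* a SweepFinder-style single-population CLR: at grid points placed at every
  10th SNP, lineages escape a sweep of strength $\alpha$ with probability
  $e^{-\alpha d}$ ($d$ in kb; $\alpha$ on a log grid from $10^{-2}$ to
  $10^4$); escaped lineages draw from the background spectrum, swept
  lineages carry the derived allele. The per-window value is the maximum
  over grid points inside the window. At $\alpha \to 0$ the sweep model
  collapses onto the background, so the CLR is nested and non-negative;
* a VarLD-style LD contrast: per population the window's signed genotype
  correlation matrix, eigenvalues in decreasing order, raw score
  $\sum_k |\lambda_{1k} - \lambda_{2k}|$, standardized genome-wide.

The 2d-SFS and sweep CLRs are simplified reimplementations of the cited
approaches, validated by simulation calibration (stable null quantiles,
localization of planted sweeps), not by binary-level equivalence with the
original programs. Monomorphic SNPs within a population enter a window's
correlation matrix as zero-correlation rows with unit diagonal.

# Outlier calling and candidate genes

Scan candidates are windows at or beyond the empirical 99.9th percentile of
any pairwise metric (DD at or below the 0.1st; the empirical quantile is
nearest-rank with ties included, because candidate counts depend on the
definition). The divergence-signature flavour uses the 99.5th percentile
over AFD, $d_{XY}$, $F_{ST}$, DD and Tajima's $D$, but only $d_{XY}$,
$F_{ST}$ and DD confer gene candidacy; AFD and Tajima's $D$ calls are
reported as supporting evidence. A gene is attached to a call when its span
intersects the window's genomic span (closed intervals).

Variant effects are predicted from the annotation in the spirit of SnpEff:
coding SNPs are translated ref-vs-alt strand-aware; intronic SNPs within 2
nt of an exon boundary are splice-disrupting; CDS indels are frameshift
when the length difference is not divisible by three. HIGH impact means
premature stop, start/stop loss, frameshift or splice disruption. The
large-effect screen retains genes with at least one HIGH-impact variant at
AFD above 0.9 between the contrast's populations; the AFD of each hit is
always reported because biologically convincing hits can sit just below
the cutoff (the screen's threshold is configurable).

Manual curation of candidate lists is replaced by declared, configurable
filters: a minimum number of supporting windows, a flag for genes whose
SNP density exceeds three times the genome median (possible collapsed
paralogs), and an optional exclusion list. Flags are annotations, not
removals.

# Environmental association

The EAA is a two-step Gaussian working model in the spirit of Bayenv2.
Step one estimates the among-population covariance $\Omega$ of
standardized allele frequencies
$x_\ell = (p_\ell - \varepsilon_\ell)/\sqrt{\varepsilon_\ell(1-\varepsilon_\ell)}$
at fourfold-degenerate SNPs (the neutral proxy), with eigenvalue clipping
to restore positive semi-definiteness. Because $\varepsilon_\ell$ is the
across-population mean, centring projects out $1/P$ of the drift variance:
under independent Balding–Nichols drift $c$ the expected diagonal is
$c(P-1)/P$ and the expected off-diagonal $-c/P$; the package's tests
verify exactly this closed form.

Step two scores each SNP: $x \sim \mathcal N(\beta E, \Omega)$ with $E$ the
standardized covariate, and
$\mathrm{BF} = \frac{1}{2\beta_{\max}}\int_{-\beta_{\max}}^{\beta_{\max}}
\frac{L(\beta)}{L(0)}\,d\beta$, evaluated by a fixed 201-point grid. The
association sign is the sign of the likelihood-maximizing slope. This
replaces the original tool's MCMC over latent population frequencies; it
is validated by null calibration (the fraction of null SNPs reaching
BF $\ge$ 100 stays well below 0.5%) and by rank recovery of planted
associations, never by equivalence to the Bayenv2 binary — the BF *scale*
is approximation-specific, while the decision threshold BF $\ge$ 100 is
retained.

The slope prior half-width defaults to $\beta_{\max} = 1$. The choice is
dictated by the operating point of the filter chain: with four populations
and drift-scale covariance, a strong M/NM frequency contrast corresponds to
standardized effects near $|\beta| \approx 1$, and a much narrower prior
truncates the likelihood mode for precisely the associations the
BF $\ge$ 100 gate is meant to retain, making the gate unreachable. A wider
prior also sharpens null calibration through the Occam factor. The value is
configurable.

The stringent chain then retains SNPs that (i) reach BF $\ge$ 100 for a
soil covariate, (ii) cause a non-synonymous change, and (iii) carry the
associated non-reference allele at higher frequency in *both* M populations
than in their respective NM populations. "Non-reference" is taken
literally (alt allele against the heterologous reference) rather than in
the polarized sense. Per contrast the Cd and Zn survivor lists are
unioned; per species the two contrasts' union lists are intersected at the
gene level. Only SNPs overlapping that contrast's divergence-signature
candidate genes are tested, mirroring the two-condition logic (divergence
signature and environmental association).

# Convergence testing

Candidate-list overlaps are tested with the exact hypergeometric upper
tail $P(X \ge k)$ — no approximation at any realistic universe size.
The default universe is the screened gene space (genes overlapped by at
least one analysis window in both contrasts), configurable to the full
annotation; the two options can be reported side by side since the
published analyses do not state their universe. Functional
over-representation per term is hypergeometric as well, reported when fold
enrichment is at least 3 and $p < 0.05$, with a Benjamini–Hochberg column
emitted for transparency. Term tables (e.g. GO biological process, levels
1–3) are supplied by the user; ontology traversal is out of scope.

# The synthetic-data generator

No reusable resequencing accession accompanies the study design this
package targets, so every stage is validated on synthetic data with
planted truth. The generator emulates the sampling structure the analysis
assumes: one species, two site pairs (populations Mias/Zapa and
Klet/Kowa), eight diploid individuals per population, genotypes drawn
binomially from hierarchical Balding–Nichols frequencies — ancestral
frequency uniform on (0.05, 0.95), pair ancestors at drift 0.2,
populations at drift 0.1 within pairs. Soil covariates carry the tenfold
M/NM contrast in exchangeable Zn and Cd (300 vs 30 and 12 vs 1.2 mg/kg).
Gene models are tiled two-exon genes with codon-valid CDS (450 + 903 bp
exons, 300 bp intron, alternating strands, one gene per 2 kb), so
classification and effect prediction are exercised for real.

Sweeps are simulated at the haplotype level: inside a sweep interval a
focal haplotype carrying the derived allele at linked sites rises to a
Beta-distributed frequency near fixation in each affected M population
(mean 0.95 at the strong setting); per-site linkage decays with distance
from the focal gene (recombination escape, to a third of its central value
at the interval edge); escaped lineages sample the pair-ancestor
frequency; and a fraction of linked sites receives one new rare ancestral
lineage, the singleton excess of a recovering sweep. Together these
reproduce the full sweep syndrome the metrics target — lowered diversity,
elevated $F_{ST}$/$d_{XY}$/AFD, negative Tajima's $D$ and $H$,
high-frequency derived excess, and local LD visible to the VarLD contrast
— which the package's rank tests verify window-wise.

What the generator does *not* emulate: coalescent genealogies (the
site-frequency spectrum is frequency-level, not genealogical, so absolute
values of $D$ and $H$ are shifted relative to coalescent expectations —
all outlier calling is empirical-quantile-based for this reason),
recombination maps, background LD outside sweeps, sequencing error and
depth variation. Passing tests therefore demonstrate correct and
calibrated *relative* behaviour of the statistics, not agreement with
coalescent theory.

The convergent fixture plants one strong sweep shared by both M
populations (spanning nine genes around a focal gene), one moderate
pair-specific sweep per pair, an environmentally associated missense SNP
riding the shared swept haplotype, a frameshift indel at AFD 0.86 (a
deliberately borderline case against the 0.9 screen), and a stop-gain SNP
at AFD 0.95 in an unswept gene. Coding SNPs inside sweep intervals are
constrained to synonymous changes so the set of non-synonymous variants in
swept genes — exactly what the stringent chain can retain — is fully
designed, making chain exactness testable.

# Numerical and design choices

* Windows default to 25 SNPs, non-overlapping; the step is configurable
  for overlapping scans.
* Quantile definition: nearest rank, ties included (both documented and
  tested, because candidate counts depend on it).
* Tajima constants at the rounded window-mean $n$; windows with no
  polymorphism give `NA` rather than 0.
* 2d-SFS projection to (10, 10) alleles with add-one pseudocounts; windows
  with fewer than 5 projectable sites are `NA`.
* Sweep CLR: escape probabilities discretized to a 121-point log grid;
  composite likelihood over 50 SNPs each side of a grid point; scaffolds
  with fewer than 25 polarized sites are skipped.
* DD regression falls back to centred diversity (with a warning) when
  $F_{ST}$ has zero variance.
* The BF quadrature is a fixed symmetric grid, making the covariate-sign
  invariance exact; a degenerate (constant) covariate is a hard error.
* Problem sizes in the test suite are desk-scale by design: the null
  calibration uses ~10,000 windows (roughly 312,000 simulated SNPs), the
  replicate suites 20 replicates at ~2,000–4,000 windows per contrast.
  These sizes give stable empirical 99.9% quantiles while keeping the
  whole suite re-runnable on a laptop.

# Known limitations

* Two-population FLK only (the LK reduction); no kinship tree.
* Haplotype-phase statistics (iHS, XP-EHH) are out of scope, as is the
  original VarLD normalization.
* The EAA Gaussian working model shares information across populations
  only through $\Omega$; with four populations its power is limited, which
  is the motive for the stringent multi-gate chain.
* Effect prediction handles one alternate allele per site and flags
  variants spanning exon boundaries conservatively as frameshift-like.
* The reference-as-ancestral polarization misassigns derived states at
  sites where the reference lineage itself carries the derived allele;
  Fay & Wu's $H$ inherits this noise, which empirical-quantile calling
  absorbs.
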