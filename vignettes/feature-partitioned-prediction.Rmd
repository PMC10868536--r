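---
title: "Feature-partitioned genomic prediction: models, simulator and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-partitioned genomic prediction: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featuregp)
```

## What the package does

`featuregp` predicts breeding values for quantitative traits from genome-wide
marker data, and asks whether *partitioning* the markers by biological
annotation improves prediction. The workflow it implements is the one used in
pig breeding programmes that genotype animals on a medium-density chip,
impute to sequence density, and then try to exploit the annotation of the
sequence variants:

1. adjust raw growth/ultrasound records to a common 100 kg live-weight
   endpoint and pre-correct them for fixed effects;
2. quality-control the genotypes (call rate, minor allele frequency, exact
   Hardy–Weinberg test, autosomes only);
3. classify every variant into positional genomic classes (intron,
   intergenic, 5 kb upstream/downstream flanks, UTRs, synonymous/missense)
   from gene models and the reference sequence;
4. optionally run a mixed-linear-model GWAS in a small *discovery*
   population and preselect trait-associated SNPs;
5. build genomic relationship matrices (GRMs) and estimate variance
   components by REML;
6. predict genomic breeding values (GEBV) by GBLUP or by the two-component
   genomic-feature model (GFBLUP), and measure accuracy by cross-validation.

Because the commercial genotype data this design comes from are private, the
package ships a synthetic-data generator that reproduces the *structure* of
such a study — two diverged populations, LD decaying over tens of kb,
class-annotated variants, traits of moderate heritability with optionally
class-enriched causal variants — so every stage is testable end to end.

## Models

### GBLUP

The single-component model for corrected phenotypes $y_c$ is

$$ y_c = 1\mu + g + e, \qquad
   g \sim N(0, G\sigma_g^2), \quad e \sim N(0, I\sigma_e^2), $$

where $G$ is VanRaden's method-1 GRM,
$G = ZZ' / \big(2\sum_j p_j(1-p_j)\big)$, with $Z$ the dosage matrix centred
at twice the observed alternate-allele frequency $p_j$; missing dosages are
replaced by $2p_j$ and therefore contribute nothing after centring. Under
Hardy–Weinberg equilibrium the diagonal of $G$ has expectation 1, which the
test suite checks by simulation.

GEBV for unphenotyped (validation) animals are conditional expectations
under joint normality,

$$ \hat g_{\text{val}} = \sigma_g^2\, G_{vr} V_{rr}^{-1} (y_r - \hat\mu),
   \qquad V_{rr} = G_{rr}\sigma_g^2 + I\sigma_e^2, $$

which is algebraically the mixed-model-equation solution with missing
records; the test suite verifies both that equivalence and the equivalence
with marker-effect ridge regression (SNP-BLUP) back-mapped to individuals.

### GFBLUP

The feature model splits the genome into a *feature* marker set (an
annotation class, or GWAS-significant SNPs) and the *remainder*:

$$ y_c = 1\mu + f + r + e, \qquad
   f \sim N(0, G_f\sigma_f^2), \quad r \sim N(0, G_r\sigma_r^2). $$

After estimating $(\sigma_f^2, \sigma_r^2, \sigma_e^2)$ the two matrices are
collapsed into one,

$$ G_{\text{Total}} = \lambda G_f + (1-\lambda) G_r, \qquad
   \lambda = \frac{\sigma_f^2}{\sigma_f^2 + \sigma_r^2}, $$

and prediction proceeds exactly as GBLUP with $G_{\text{Total}}$ and total
genetic variance $\sigma_f^2 + \sigma_r^2$. $G_f$ and $G_r$ are each scaled
by their own $2\sum p(1-p)$ so both have expectation-1 diagonals; the
$\lambda$-weighting assumes comparable scales, and mixing matrices scaled by
different denominators would make $\lambda$ uninterpretable. When the
feature panel is layered on top of a base panel (chip data), variants
present in both components are first removed from the feature panel so no
marker enters the model twice.

If $G_f = G_r$ numerically, only $\sigma_f^2 + \sigma_r^2$ is identifiable.
`reml_two()` detects this (Frobenius distance below $10^{-10}$ relative)
and flags the fit rather than reporting an arbitrary $\lambda$; GFBLUP
scenarios abort on that flag.

### REML

`reml_single()` eigendecomposes $G$ once and profiles the restricted
likelihood down to the single ratio $\delta = \sigma_e^2/\sigma_g^2$,
maximised by an 81-point log-grid scan over $[10^{-6}, 10^6]$ followed by
golden-section refinement between the bracketing grid points. The grid stage
makes the search robust to the flat, occasionally bimodal profiles that
low-information data produce; the refinement brings the optimum to within
$10^{-10}$ on the log scale. The phenotype is standardised internally (and
rounded to 12 significant digits) so that affinely equivalent phenotypes
follow bit-identical optimisation paths; components are rescaled on exit.

`reml_two()` uses average-information (AI) updates with EM fallback: the
first 3 iterations are EM, after which AI steps are taken whenever they do
not decrease the restricted likelihood and keep all components above the
floor of $10^{-8}\,\mathrm{var}(y)$; otherwise the EM step (with step
halving) is used. Accepted iterations therefore never decrease the
likelihood. Convergence requires $|\Delta \log L| < 10^{-8}$ and a maximum
relative component change below $10^{-6}$, within a cap of 100 iterations;
non-convergence is reported, not hidden. Components pinned at the floor are
flagged as boundary-constrained.

### GWAS and the preselection rule

`mlm_gwas()` uses the fixed-null approximation standard in large-scale
mixed-model association: the null variance components are estimated once,
$V = G\hat\sigma_g^2 + I\hat\sigma_e^2$ is held fixed, and each variant is
tested by generalised least squares after a single eigendecomposition of
$G$, giving a 1-df Wald chi-square. The candidate variant remains in the
GRM (no leave-one-chromosome-out); the resulting proximal contamination is
accepted and documented, matching the tooling convention this workflow
follows. Monomorphic variants are flagged untested rather than dropped.

Preselection uses the study-specific FDR rule
$p_{\text{threshold}} = \mathrm{FDR} \times N/M$, where $N$ is the number of
variants with $p < 0.05$ and $M$ the total tested. This is deliberately
**not** Benjamini–Hochberg; a BH option exists behind
`fdr_threshold(..., method = "bh")` for comparison and is off by default.
When every variant has $p < 0.05$ the threshold equals the nominal FDR.

### Cross-validated accuracy

`crossvalidate()` partitions individuals into 5 near-equal folds (sizes
differ by at most 1), re-estimates variance components on the training
folds only — $\lambda$ included, so no information leaks from validation
animals — predicts the held-out fold, and reports the Pearson correlation
between GEBV and corrected phenotypes, averaged over all rounds with its
empirical standard error. Accuracy is the raw correlation, not divided by
$h$. The fold draw is seeded and recorded, so scenario comparisons can be
made on *paired* folds; `compare_scenarios()` refuses unpaired structures.
The repeat count is configurable (`n_repeats`); a single repetition of
5 folds is the default.

## The synthetic-data generator

`simulate_dataset()` produces a reference genome, gene models, two-density
genotype panels for several populations, class annotations and phenotypes:

* **Genome and genes.** Random nucleotide chromosomes; non-overlapping
  genes on both strands, each with a 5′UTR, 1–3 introns, a CDS that starts
  with ATG, ends with a stop and contains no internal stop (the CDS bases
  are written into the reference, reverse-complemented on the minus
  strand), and a 3′UTR. At least 40% of the genome remains intergenic. With
  the default geometry (3 chromosomes × 3 Mb, 60 genes) intron plus
  intergenic labels cover ≳ 90% of variants and the 5 kb flanks a few
  percent each, qualitatively matching the class proportions reported for
  real sequence data where introns and intergenic regions dominate.
* **Genotypes.** Ancestral allele frequencies Uniform(0.05, 0.95);
  per-population frequencies from the Balding–Nichols model at divergence
  `fst` (default 0.10, giving clearly separated identity-by-state
  distributions). Each population has a small founder pool of haplotypes
  (default 4, reproducing the strong short-range LD — $r^2 \approx 0.3$
  below 10 kb — typical of intensively selected livestock with small
  effective population size); individual haplotypes are block-wise mosaics
  of founders with switch probability
  $1-\exp(-d/\text{ld\_block\_bp})$ between adjacent variants (default
  block scale 50 kb), so $r^2$ decays smoothly over tens of kb;
  `ld_block_bp = 0` disables LD. Genotypes are sums of two
  independent haplotypes, hence in Hardy–Weinberg proportions within
  population. The chip panel is an evenly spaced subsample of the dense
  variant positions, mimicking a 50K chip against sequence data. A default
  1% of genotype calls are set missing to exercise QC.
* **Phenotypes.** Six growth-trait columns by default, each with `n_qtl`
  causal variants drawn uniformly or enriched in a named genomic class,
  Gaussian effects (matching the infinitesimal assumption GBLUP makes, so
  parameter recovery is a fair test), residual variance set so the realized
  narrow-sense heritability equals `h2_target` (default 0.30, the middle of
  the 0.2–0.4 range typical for pig growth traits). Sex (Bernoulli 0.5) and
  population enter as fixed effects; raw "measured" weight/age/backfat/loin
  columns are emitted for the endpoint-adjustment functions.

What the generator does **not** emulate: realistic recombination maps or
MAF spectra, pedigree structure, selection, genotyping error or imputation
error (imputation is outside the package's scope). Tests passing on this
generator demonstrate the estimators' correctness under their own
assumptions — Gaussian architecture, causal variants inside the marker
panel — not their field performance on real livestock data, where causal
variants are imperfectly tagged and architectures are not Gaussian.

## Phenotype adjustment

The endpoint-adjustment equations standardise records to 100 kg live
weight. Age: $\mathrm{AGE}_{100} = \text{age} - (\text{weight}-100)/CF$
with $CF = (\text{weight}/\text{age}) \times 1.826$ (sire line) or
$\times 1.715$ (dam line). Gain: $\mathrm{ADG}_{100} = 100/\mathrm{AGE}_{100}$.
Backfat and loin depth use the ratio form $x \cdot A/(A + B(\text{weight}-100))$
with the published sire/dam constants (BF: 13.47/0.1115 and 15.65/0.1566;
LMD: 50.52/0.228 and 52.01/0.228). Lean meat percentage is the affine
function $61.21920 - 0.77665\,\mathrm{BF} + 0.15239\,\mathrm{LMD}$.

Two interpretation choices are worth flagging. First, the LMP equation is
evaluated on the *adjusted* BF and LMD: the equation is labelled as an
adjustment to 100 kg, so its inputs are taken to be the 100 kg-adjusted
values (the published equation writes bare "BF" and "LMD"). Second, the sire/dam
constant pairs are mapped to animal sex (male → sire-line, female →
dam-line constants), the usual convention where terminal-line males and
maternal-line females are performance-tested. All adjustments reduce to the
identity at a measured weight of exactly 100 kg, which the tests assert.

Fixed-effect pre-correction replaces a dedicated BLUP pre-processor with
ordinary least-squares residualisation plus the re-added grand mean; for a
purely fixed model the two coincide, and the corrected phenotype keeps the
phenotype mean to machine precision.

## QC conventions

The thresholds default to the standard chip-QC quadruple: individual call
rate > 0.90, variant call rate > 0.90, MAF > 0.05, exact-test HWE
$p > 10^{-6}$, autosomes only. Inequalities are strict — a variant with MAF
exactly 0.05 fails — reading the published thresholds literally. The HWE
test is the exact conditional test computed by the heterozygote-count
recurrence, two-sided, without mid-p correction, the dominant convention in
genotype-QC tooling; the suite checks it against brute-force enumeration to
$10^{-12}$. Filters run individuals first, then variants (call rate → MAF →
HWE), because allele frequencies change after individual removal; the
variant filter itself is idempotent. HWE is tested within each population
by default (a variant failing in any population fails), with a pooled
option.

## Numerical choices and degenerate inputs

* GRM inversion never happens on the stored matrix; a $10^{-6}$ ridge is
  applied at solve time only if the reference block is numerically
  singular, and the event is reported.
* Eigenvalues of $G$ below 0 (possible from accumulated rounding) are
  floored at 0 inside REML, with a message if the violation exceeds
  tolerance.
* An all-monomorphic marker set makes the VanRaden denominator zero and is
  an explicit error, as are empty panels after intersection/deduplication,
  zero survivors of QC, and gene densities that cannot be placed on the
  requested genome.
* Variant identity is always the `(chrom, pos, ref, alt)` tuple; positions
  alone collide at multiallelic sites. GFF3 and VCF coordinates are 1-based
  inclusive end to end.
* Panels are drawn with `sample()` under a caller-supplied seed and stored
  with their provenance (source, class or discovery population, seed), so
  any panel can be reconstructed exactly.

## Problem sizes used by the test suite

The validation suite states its own scale: formula oracles run on hand-size
inputs; simulation-based checks use populations of 300–1200 individuals and
250–5000 variants, chosen so each check has enough power to be meaningful
(20 replicates for stochastic bands) while the whole suite stays
desk-scale. Single-component heritability recovery uses n = 1200,
m = 4000 over 20 replicates; feature-weight recovery uses n = 800
(enrichment) and n = 600 (even split); GWAS calibration n = 800, m = 3000
over 20 permutation replicates; the scenario-level comparisons n = 400,
m = 2500 over 20 paired seeds. These are deliberate scaled-down analogues
of the study design (thousands of animals, millions of variants): the
estimators are size-agnostic, and the statistical behaviour being checked —
unbiasedness, calibration, ordering of scenarios — is already visible at
this scale.

## Known limitations

* Single-trait models only; no multi-trait REML, no more than two genomic
  components, no Bayesian alphabet.
* The GWAS keeps the tested variant inside the GRM (proximal
  contamination), as the standard fixed-null tooling does.
* The positional classifier handles one coding transcript per gene;
  splice/start/stop sub-classes and frameshift/inframe INDEL calls are out
  of scope (INDELs inside a CDS are labelled positionally).
* Imputation, and imputation-error modelling, are out of scope; the
  generator's two marker densities stand in for "chip" and "imputed
  sequence" panels without an error process between them.
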