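# featuregp

Feature-partitioned genomic prediction for quantitative traits: GBLUP,
genomic-feature BLUP (GFBLUP), REML variance components, mixed-model GWAS
with FDR preselection, positional variant annotation, genotype QC,
endpoint adjustment of pig growth traits, and a two-population
genotype/phenotype simulator that makes the whole pipeline testable
without access to commercial genotype data.

## The problem

Breeding programmes predict an animal's genetic merit (its genomic
estimated breeding value, GEBV) from genome-wide markers. Sequence-density
genotypes should in principle beat a 50K chip — they contain the causal
variants — yet in practice rarely do. One remedy is to give *prioritised*
markers (an annotation class such as introns or UTRs, or GWAS-significant
SNPs from an independent discovery population) their own variance
component. `featuregp` implements both the baseline and the partitioned
model:

- **GBLUP**: `y_c = 1μ + g + e`, `g ~ N(0, G σg²)`, with `G` the VanRaden
  genomic relationship matrix `ZZ' / (2Σ p(1−p))`.
- **GFBLUP**: `y_c = 1μ + f + r + e` with feature and remainder components
  `f ~ N(0, G_f σf²)`, `r ~ N(0, G_r σr²)`, collapsed for prediction into
  `G_Total = λ G_f + (1−λ) G_r`, `λ = σf² / (σf² + σr²)`.

Variance components come from REML (profiled eigendecomposition form for
one component; average-information with EM fallback for two). Prediction
accuracy is the cross-validated correlation between GEBV and corrected
phenotypes. GWAS preselection uses the study-specific threshold
`p = FDR × N/M` (N = markers with p < 0.05, M = total), not
Benjamini–Hochberg.

Who this is for: quantitative geneticists and breeding-programme analysts
who want a self-contained, tested R implementation of the
annotation-partitioned prediction workflow, plus a simulator for method
development.

## Worked example

```r
library(featuregp)

# a synthetic study: one validation and one discovery population,
# sequence-density and chip-density panels, six growth traits (h2 = 0.3),
# QTL enriched in introns
cfg <- sim_config(seed = 7, n_individuals = c(val = 300, disc = 150),
                  n_variants_dense = 4000, n_variants_chip = 800,
                  n_genes = 40, qtl_class = "intron",
                  qtl_class_fraction = 1, n_qtl = 50)
ds <- simulate_dataset(cfg)
ds
#> sim_dataset: 450 individuals; 4000 dense / 800 chip variants; 40 genes; 6 traits

# endpoint adjustment of the raw measured records
head(adjust_growth_traits(ds$phenotypes)[, c("age_adj", "bf_adj", "lmp_adj")], 3)
#>    age_adj   bf_adj  lmp_adj
#> 1 140.8213 11.57769 60.56134
#> 2 170.6895 15.87521 56.73300
#> 3 156.0318 11.84278 60.36379

# baseline GBLUP on the dense panel vs GFBLUP with the intron panel,
# cross-validated on paired folds
base <- run_scenario(ds, "gblup_dense", traits = "ADG", seed = 1)
feat <- run_scenario(ds, "gfblup_dense", traits = "ADG",
                     panel_class = "intron", seed = 1)
compare_scenarios(list(base, feat))[, c("scenario", "mean_accuracy",
                                        "baseline_accuracy", "mean_diff")]
#>       scenario mean_accuracy baseline_accuracy mean_diff
#> 1 gfblup_dense     0.3422822        0.02112496 0.3211573
```

The comparison says: at this small training size the undifferentiated
dense-panel GBLUP barely predicts this trait (accuracy 0.02), because the
50 causal intron variants are drowned among 4000 markers; giving the
intron class its own variance component lifts the cross-validated accuracy
to 0.34 — the feature model's advantage when the annotation genuinely
carries the signal. With uniformly placed QTL the two scenarios coincide
to within sampling noise.

Lower-level entry points: `qc_genotypes()`, `classify_variants()`,
`build_class_panels()`, `mlm_gwas()` + `fdr_threshold()` +
`select_significant()`, `vanraden_grm()`, `reml_single()` / `reml_two()`,
`gblup_fit()` / `gfblup_fit()`, `crossvalidate()`. File I/O:
`read_vcf()` / `write_vcf()`, `read_gff3()` / `write_gff3()`.

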