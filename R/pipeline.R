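SCENARIOS <- c("gblup_chip", "gblup_dense", "gblup_class",
               "gfblup_chip", "gfblup_dense")

light_checksum <- function(x) {
  s <- paste(x, collapse = "|")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647)
}

#' Run one genomic-prediction scenario end to end
#'
#' Executes the stage chain QC -> panel construction (annotation or
#' GWAS preselection) -> GRM -> variance components -> cross-validated
#' prediction on one validation population of a dataset. The five
#' scenario families are: `gblup_chip` (chip-density GRM),
#' `gblup_dense` (sequence-density GRM), `gblup_class` (GRM from one
#' genomic-class panel), `gfblup_chip` (feature panel + chip as two
#' components; the panel is first purged of chip duplicates) and
#' `gfblup_dense` (feature panel + remaining dense markers).
#'
#' @param data a `sim_dataset` from [simulate_dataset()], or a list with
#'   the same elements (`dense`, `chip`, `classes`, `phenotypes`).
#' @param scenario one of the five scenario names.
#' @param traits trait columns of `data$phenotypes` to analyse.
#' @param validation_population population whose individuals are
#'   cross-validated; default the first population.
#' @param panel a [panel_spec()] used as the feature/class panel, or
#'   `NULL` to build one from `panel_class` / `discovery_population`.
#' @param panel_class genomic class label used to build the panel.
#' @param discovery_population if given (and `panel_class` is `NULL`),
#'   the feature panel is the GWAS-significant set discovered in this
#'   population (per trait).
#' @param fdr nominal FDR for GWAS preselection.
#' @param n_folds,n_repeats,seed cross-validation settings (see
#'   [crossvalidate()]).
#' @param qc a [qc_thresholds()].
#' @param lambda_override optional fixed lambda forced into GFBLUP
#'   scenarios instead of the REML estimate (0 reduces GFBLUP to GBLUP
#'   on `Gr`).
#' @return List of class `scenario_result`: `table` (one row per trait:
#'   scenario, trait, panel, mean_accuracy, se), `cv` (named list of
#'   `cv_result`), `provenance` (seeds, marker counts, checksums).
#' @export
run_scenario <- function(data, scenario = SCENARIOS, traits = NULL,
                         validation_population = NULL,
                         panel = NULL, panel_class = NULL,
                         discovery_population = NULL, fdr = 0.05,
                         n_folds = 5, n_repeats = 1, seed = 1,
                         qc = qc_thresholds(),
                         lambda_override = NULL) {
  scenario <- match.arg(scenario)
  pops <- unique(data$dense$samples$population)
  if (is.null(validation_population)) validation_population <- pops[1]
  if (is.null(traits)) traits <- data$config$trait_set
  val_idx <- which(data$dense$samples$population == validation_population)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  dense <- stage("qc_dense", qc_genotypes(
    subset_genotypes(data$dense, individuals = val_idx), qc))
  chip <- stage("qc_chip", qc_genotypes(
    subset_genotypes(data$chip, individuals = val_idx), qc))
  ph <- data$phenotypes[match(dense$samples$id, data$phenotypes$id), ]
  covars <- data.frame(sex = ph$sex)
  needs_panel <- scenario %in% c("gblup_class", "gfblup_chip",
                                 "gfblup_dense")
  get_panel <- function(trait) {
    if (!needs_panel) return(NULL)
    if (!is.null(panel)) return(panel)
    if (!is.null(panel_class)) {
      return(stage("panel_class",
                   build_class_panels(data$classes, panel_class,
                                      target_size = "min",
                                      seed = seed)[[panel_class]]))
    }
    if (!is.null(discovery_population)) {
      return(stage("panel_gwas",
                   gwas_panel(data, trait, discovery_population, fdr,
                              qc)))
    }
    stop("scenario '", scenario,
         "' needs a panel, panel_class or discovery_population")
  }
  cvs <- list()
  rows <- list()
  for (trait in traits) {
    yc <- precorrect_fixed_effects(ph[[trait]], covars)
    names(yc) <- ph$id
    pn <- get_panel(trait)
    res <- stage(scenario, switch(
      scenario,
      gblup_chip = cv_single(yc, chip, n_folds, n_repeats, seed, scenario),
      gblup_dense = cv_single(yc, dense, n_folds, n_repeats, seed,
                              scenario),
      gblup_class = {
        pn2 <- intersect_panels(pn, dense)
        cv_single(yc, subset_genotypes(dense, variants = pn2$ids),
                  n_folds, n_repeats, seed, scenario)
      },
      gfblup_chip = {
        pn2 <- deduplicate_against_base(intersect_panels(pn, dense), chip)
        if (!length(pn2$ids))
          stop("feature panel empty after intersection/deduplication")
        cv_two(yc, subset_genotypes(dense, variants = pn2$ids), chip,
               n_folds, n_repeats, seed, scenario, lambda_override)
      },
      gfblup_dense = {
        pn2 <- intersect_panels(pn, dense)
        rest <- setdiff(dense$variants$id, pn2$ids)
        if (!length(rest)) stop("no markers left outside the panel")
        cv_two(yc, subset_genotypes(dense, variants = pn2$ids),
               subset_genotypes(dense, variants = rest),
               n_folds, n_repeats, seed, scenario, lambda_override)
      }))
    cvs[[trait]] <- res
    rows[[trait]] <- data.frame(
      scenario = scenario, validation_population = validation_population,
      trait = trait,
      panel = if (is.null(pn)) NA_character_ else pn$name,
      panel_size = if (is.null(pn)) NA_integer_ else length(pn$ids),
      mean_accuracy = res$mean_accuracy, se = res$se,
      stringsAsFactors = FALSE)
  }
  structure(list(
    table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    cv = cvs,
    provenance = list(
      scenario = scenario, seed = seed, n_folds = n_folds,
      n_repeats = n_repeats, fdr = fdr,
      validation_population = validation_population,
      n_dense = ncol(dense$geno), n_chip = ncol(chip$geno),
      dense_checksum = light_checksum(dense$variants$id),
      chip_checksum = light_checksum(chip$variants$id),
      pheno_checksum = light_checksum(round(unlist(
        data$phenotypes[traits]), 6)))),
    class = "scenario_result")
}

cv_single <- function(yc, geno, n_folds, n_repeats, seed, scenario) {
  G <- vanraden_grm(geno)
  crossvalidate(yc, G = G, n_folds = n_folds, n_repeats = n_repeats,
                seed = seed, scenario = scenario)
}

cv_two <- function(yc, geno_f, geno_r, n_folds, n_repeats, seed, scenario,
                   lambda_override = NULL) {
  Gf <- vanraden_grm(geno_f)
  Gr <- vanraden_grm(geno_r)
  if (!is.null(lambda_override)) {
    # fixed-lambda variant: combine once, then single-component CV
    Gt <- combine_grm(Gf, Gr, lambda_override)
    return(crossvalidate(yc, G = Gt, n_folds = n_folds,
                         n_repeats = n_repeats, seed = seed,
                         scenario = scenario))
  }
  crossvalidate(yc, Gf = Gf, Gr = Gr, n_folds = n_folds,
                n_repeats = n_repeats, seed = seed, scenario = scenario)
}

# GWAS preselection panel from a discovery population
gwas_panel <- function(data, trait, discovery_population, fdr = 0.05,
                       qc = qc_thresholds()) {
  disc_idx <- which(data$dense$samples$population == discovery_population)
  if (!length(disc_idx))
    stop("no individuals in discovery population '",
         discovery_population, "'")
  disc <- qc_genotypes(subset_genotypes(data$dense,
                                        individuals = disc_idx), qc)
  ph <- data$phenotypes[match(disc$samples$id, data$phenotypes$id), ]
  yc <- precorrect_fixed_effects(ph[[trait]],
                                 data.frame(sex = ph$sex))
  G <- vanraden_grm(disc)
  gw <- mlm_gwas(yc, disc, G)
  thr <- fdr_threshold(gw$p, fdr)
  select_significant(gw, thr, discovery = discovery_population,
                     trait = trait)
}

#' Compare scenarios by paired fold differences
#'
#' All results must share fold structure (same seed, folds, repeats) so
#' differences are paired. The first result is the baseline; for every
#' other scenario the per-round accuracy differences, their mean, and
#' the percent improvement of the mean accuracy over the baseline are
#' reported per trait.
#'
#' @param results named list of `scenario_result` objects (first =
#'   baseline).
#' @return data.frame: scenario, trait, baseline, mean_accuracy,
#'   mean_diff, pct_improvement, n_rounds.
#' @export
compare_scenarios <- function(results) {
  stopifnot(length(results) >= 2)
  base <- results[[1]]
  key <- function(r) unlist(r$provenance[c("seed", "n_folds", "n_repeats")])
  rows <- list()
  for (k in seq(2, length(results))) {
    other <- results[[k]]
    if (!identical(key(base), key(other)))
      stop("unpaired fold structures between '",
           base$provenance$scenario, "' and '",
           other$provenance$scenario, "'")
    for (trait in names(base$cv)) {
      if (!trait %in% names(other$cv)) next
      a <- base$cv[[trait]]$folds$accuracy
      b <- other$cv[[trait]]$folds$accuracy
      stopifnot(length(a) == length(b))
      rows[[length(rows) + 1]] <- data.frame(
        scenario = other$provenance$scenario, trait = trait,
        baseline = base$provenance$scenario,
        baseline_accuracy = mean(a, na.rm = TRUE),
        mean_accuracy = mean(b, na.rm = TRUE),
        mean_diff = mean(b - a, na.rm = TRUE),
        pct_improvement = 100 * (mean(b, na.rm = TRUE) -
                                   mean(a, na.rm = TRUE)) /
          abs(mean(a, na.rm = TRUE)),
        n_rounds = sum(!is.na(b - a)), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
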