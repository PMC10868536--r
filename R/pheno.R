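#' Weight-endpoint adjustment constants for pig growth traits
#'
#' Constants used to standardise growth and ultrasound carcass traits to a
#' 100 kg live-weight endpoint. The age correction-factor multiplier and the
#' backfat (BF) / loin muscle depth (LMD) ratio constants differ between
#' sire-line and dam-line animals; the lean meat percentage (LMP) equation
#' is a fixed affine function of adjusted BF and LMD.
#'
#' @format A list with elements `age_multiplier`, `bf`, `lmd` (each a list
#'   with `sire` and `dam` entries) and `lmp` (intercept and coefficients).
#' @export
adjustment_constants <- list(
  age_multiplier = c(sire = 1.826, dam = 1.715),
  bf  = list(sire = c(A = 13.47, B = 0.1115), dam = c(A = 15.65, B = 0.1566)),
  lmd = list(sire = c(A = 50.52, B = 0.228),  dam = c(A = 52.01, B = 0.228)),
  lmp = c(intercept = 61.21920, bf = -0.77665, lmd = 0.15239)
)

check_sex <- function(sex) {
  sex <- as.character(sex)
  if (!all(sex %in% c("sire", "dam")))
    stop("sex must be 'sire' or 'dam'")
  sex
}

#' Adjust days-to-weight (AGE) to the 100 kg endpoint
#'
#' `AGE_100 = measured_age - (measured_weight - 100) / CF` with correction
#' factor `CF = (measured_weight / measured_age) * multiplier(sex)`
#' (1.826 for sire-line, 1.715 for dam-line animals). At a measured weight
#' of exactly 100 kg the adjustment is the identity.
#'
#' @param measured_weight live weight at measurement, kg (> 0).
#' @param measured_age age at measurement, days (> 0).
#' @param sex `"sire"` or `"dam"` (vectorised).
#' @return Adjusted age in days.
#' @export
adjust_age <- function(measured_weight, measured_age, sex) {
  sex <- check_sex(sex)
  if (any(!is.finite(measured_weight)) || any(measured_weight <= 0))
    stop("measured_weight must be positive")
  if (any(!is.finite(measured_age)) || any(measured_age <= 0))
    stop("measured_age must be positive")
  cf <- (measured_weight / measured_age) *
    adjustment_constants$age_multiplier[sex]
  unname(measured_age - (measured_weight - 100) / cf)
}

#' Adjust average daily gain (ADG) to the 100 kg endpoint
#'
#' `ADG_100 = 100 / AGE_100` (kg/day), strictly decreasing in adjusted age.
#'
#' @param adjusted_age age adjusted to 100 kg, days (> 0).
#' @return Adjusted average daily gain, kg/day.
#' @export
adjust_adg <- function(adjusted_age) {
  if (any(!is.finite(adjusted_age)) || any(adjusted_age <= 0))
    stop("adjusted_age must be positive")
  100 / adjusted_age
}

#' Adjust an ultrasound ratio trait (BF or LMD) to the 100 kg endpoint
#'
#' `x_100 = x * A / (A + B * (measured_weight - 100))` with `(A, B)` chosen
#' by trait and sex line (Canadian Centre for Swine Improvement factors).
#' Identity at a measured weight of 100 kg.
#'
#' @param trait `"bf"` (backfat, mm) or `"lmd"` (loin muscle depth, mm).
#' @param measured_value measured trait value, mm.
#' @param measured_weight live weight at measurement, kg.
#' @param sex `"sire"` or `"dam"` (vectorised).
#' @return Adjusted trait value, mm.
#' @export
adjust_ratio_trait <- function(trait = c("bf", "lmd"), measured_value,
                               measured_weight, sex) {
  trait <- match.arg(trait)
  sex <- check_sex(sex)
  cst <- adjustment_constants[[trait]]
  A <- vapply(sex, function(s) cst[[s]][["A"]], numeric(1))
  B <- vapply(sex, function(s) cst[[s]][["B"]], numeric(1))
  den <- A + B * (measured_weight - 100)
  if (any(!is.finite(den)) || any(den <= 0))
    stop("nonpositive adjustment denominator at measured_weight = ",
         paste(measured_weight[!is.finite(den) | den <= 0], collapse = ", "))
  unname(measured_value * A / den)
}

#' Adjusted lean meat percentage (LMP)
#'
#' `LMP_100 = 61.21920 - 0.77665 * BF + 0.15239 * LMD`, evaluated on the
#' 100 kg-adjusted backfat and loin muscle depth. Affine: one extra mm of
#' backfat always lowers LMP by exactly 0.77665 percentage points; one
#' extra mm of loin depth raises it by 0.15239.
#'
#' @param adjusted_bf backfat adjusted to 100 kg, mm.
#' @param adjusted_lmd loin muscle depth adjusted to 100 kg, mm.
#' @return Lean meat percentage.
#' @export
adjust_lmp <- function(adjusted_bf, adjusted_lmd) {
  if (any(!is.finite(adjusted_bf)) || any(!is.finite(adjusted_lmd)))
    stop("inputs must be finite")
  k <- adjustment_constants$lmp
  unname(k[["intercept"]] + k[["bf"]] * adjusted_bf + k[["lmd"]] * adjusted_lmd)
}

#' Adjust all measured growth traits in a phenotype table
#'
#' Applies [adjust_age()], [adjust_adg()], [adjust_ratio_trait()] and
#' [adjust_lmp()] to a table of measured records, appending `_adj` columns.
#'
#' @param pheno data.frame with columns `sex` (`"sire"`/`"dam"`),
#'   `measured_weight_kg`, `measured_age_d`, `measured_bf_mm`,
#'   `measured_lmd_mm`.
#' @return The input with columns `age_adj`, `adg_adj`, `bf_adj`,
#'   `lmd_adj`, `lmp_adj` appended.
#' @export
adjust_growth_traits <- function(pheno) {
  req <- c("sex", "measured_weight_kg", "measured_age_d", "measured_bf_mm",
           "measured_lmd_mm")
  miss <- setdiff(req, names(pheno))
  if (length(miss)) stop("phenotype table lacks column(s): ",
                         paste(miss, collapse = ", "))
  pheno$age_adj <- adjust_age(pheno$measured_weight_kg, pheno$measured_age_d,
                              pheno$sex)
  pheno$adg_adj <- adjust_adg(pheno$age_adj)
  pheno$bf_adj <- adjust_ratio_trait("bf", pheno$measured_bf_mm,
                                     pheno$measured_weight_kg, pheno$sex)
  pheno$lmd_adj <- adjust_ratio_trait("lmd", pheno$measured_lmd_mm,
                                      pheno$measured_weight_kg, pheno$sex)
  pheno$lmp_adj <- adjust_lmp(pheno$bf_adj, pheno$lmd_adj)
  pheno
}

#' Pre-correct phenotypes for fixed effects
#'
#' Ordinary least-squares residualisation: fits `y ~ covariates` (factors
#' expanded to dummies, collinear columns dropped with a message) and
#' returns residuals plus the grand mean, so the corrected phenotype keeps
#' the original mean. With no covariates the phenotype is returned as is.
#'
#' @param y numeric phenotype vector (`NA` allowed; corrected values are
#'   `NA` where `y` is).
#' @param covariates data.frame of fixed-effect columns (factors or
#'   numeric), or `NULL`.
#' @return Numeric vector `y_c` of fixed-effect-corrected phenotypes,
#'   same length and mean as `y`.
#' @export
precorrect_fixed_effects <- function(y, covariates = NULL) {
  y <- as.numeric(y)
  if (is.null(covariates) || NCOL(covariates) == 0) return(y)
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y))
  X <- stats::model.matrix(~ ., data = covariates)
  ok <- !is.na(y) & complete.cases(covariates)
  fit <- lm.fit(X[ok, , drop = FALSE], y[ok])
  if (any(is.na(fit$coefficients))) {
    dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
    message("dropped collinear column(s): ", paste(dropped, collapse = ", "))
  }
  yc <- rep(NA_real_, length(y))
  yc[ok] <- fit$residuals + mean(y[ok])
  yc
}
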