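#' GBLUP fit and prediction of unphenotyped individuals
#'
#' With reference phenotypes `y_ref` and a GRM spanning reference plus
#' validation individuals, the overall mean is estimated by generalized
#' least squares on the reference block and breeding values are the
#' conditional expectations
#' `g_hat = sigma_g2 * G[, ref] V_rr^-1 (y_ref - mu)` with
#' `V_rr = G_rr sigma_g2 + I sigma_e2`. Reference and validation animals
#' both receive GEBV. A 1e-6 diagonal ridge is applied only if `V_rr` is
#' numerically singular.
#'
#' @param y_ref named numeric vector of reference phenotypes; names must
#'   match rownames of `G`.
#' @param G `grm` over reference and validation individuals.
#' @param vc `varcomp` fit (single component, or two-component: the
#'   genetic variance used is then `sigma_f2 + sigma_r2`).
#' @param validation_ids ids of unphenotyped individuals to predict
#'   (must be in `G`, must not overlap `names(y_ref)`).
#' @return List of class `mixed_model_fit`: `mu`, `gebv` (named, all
#'   individuals of `G`), `sigma_g2`, `sigma_e2`, `reference_ids`,
#'   `validation_ids`.
#' @export
gblup_fit <- function(y_ref, G, vc, validation_ids = character(0)) {
  stopifnot(!is.null(names(y_ref)), !is.null(rownames(G)))
  ref_ids <- names(y_ref)
  if (length(intersect(ref_ids, validation_ids)))
    stop("validation ids overlap reference ids")
  all_ids <- rownames(G)
  missing_ids <- setdiff(c(ref_ids, validation_ids), all_ids)
  if (length(missing_ids))
    stop("ids absent from GRM: ", paste(head(missing_ids, 3), collapse = ", "))
  sigma_g2 <- if (!is.null(vc$sigma_g2)) vc$sigma_g2
              else vc$sigma_f2 + vc$sigma_r2
  sigma_e2 <- vc$sigma_e2
  Gm <- unclass(G)
  ri <- match(ref_ids, all_ids)
  Vrr <- sigma_g2 * Gm[ri, ri, drop = FALSE] + diag(sigma_e2, length(ri))
  ch <- tryCatch(chol(Vrr), error = function(e) NULL)
  if (is.null(ch)) {
    message("singular V_rr; adding 1e-6 ridge")
    ch <- chol(Vrr + diag(1e-6, length(ri)))
  }
  Vinv <- chol2inv(ch)
  ones <- rep(1, length(ri))
  mu <- sum(Vinv %*% y_ref) / sum(Vinv)
  resid <- y_ref - mu
  gebv <- drop(sigma_g2 * Gm[, ri, drop = FALSE] %*% (Vinv %*% resid))
  names(gebv) <- all_ids
  structure(list(mu = mu, gebv = gebv, sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2, reference_ids = ref_ids,
                 validation_ids = validation_ids),
            class = "mixed_model_fit")
}

#' GFBLUP fit via the lambda-combined GRM
#'
#' Combines the feature and residual GRMs into
#' `G_Total = lambda Gf + (1 - lambda) Gr` with
#' `lambda = sigma_f2 / (sigma_f2 + sigma_r2)` from the two-component
#' REML fit, then performs exactly the [gblup_fit()] computation with
#' `G_Total` and total genetic variance `sigma_f2 + sigma_r2`.
#'
#' @inheritParams gblup_fit
#' @param Gf,Gr feature and residual `grm` matrices (identical
#'   individual order).
#' @param vc two-component `varcomp` fit estimated on the reference
#'   individuals. A non-identifiable fit (identical GRMs) aborts the
#'   scenario.
#' @return A `mixed_model_fit` (with the `lambda` used attached).
#' @export
gfblup_fit <- function(y_ref, Gf, Gr, vc, validation_ids = character(0)) {
  if (!is.null(vc$identifiable) && !vc$identifiable)
    stop("scenario aborted: lambda is not identifiable ",
         "(feature and residual GRMs are identical)")
  lam <- compute_lambda(vc)
  Gt <- combine_grm(Gf, Gr, lam)
  fit <- gblup_fit(y_ref, Gt, vc, validation_ids)
  fit$lambda <- lam
  fit
}

#' Cross-validated genomic prediction accuracy
#'
#' Individuals are randomly partitioned into `n_folds` groups of
#' near-equal size (sizes differ by at most 1); in each round, variance
#' components are re-estimated on the reference folds only (no
#' information leakage into validation), GEBV are predicted for the
#' held-out fold, and accuracy is the Pearson correlation between GEBV
#' and the held-out corrected phenotypes. The whole partition is redrawn
#' `n_repeats` times; the reported accuracy is the mean over all
#' `n_folds * n_repeats` rounds with its empirical standard error.
#'
#' @param y named numeric corrected phenotypes (names match `G`
#'   rownames).
#' @param G single-component `grm` (GBLUP scenarios), or `NULL` when
#'   `Gf`/`Gr` are supplied.
#' @param Gf,Gr feature/residual GRMs for GFBLUP scenarios.
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats of the whole partition (default 1).
#' @param seed RNG seed for the fold draw, recorded in the result.
#' @param scenario label carried into the result.
#' @return List of class `cv_result`: `folds` data.frame (repeat, fold,
#'   size, accuracy), `mean_accuracy`, `se`, plus the call's settings.
#' @export
crossvalidate <- function(y, G = NULL, Gf = NULL, Gr = NULL,
                          n_folds = 5, n_repeats = 1, seed = 1,
                          scenario = NA_character_) {
  stopifnot(n_folds >= 2, !is.null(names(y)))
  two_comp <- !is.null(Gf) && !is.null(Gr)
  if (!two_comp && is.null(G)) stop("supply G, or both Gf and Gr")
  ids <- names(y)
  n <- length(ids)
  set.seed(seed)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold_of <- sample(rep(seq_len(n_folds), length.out = n))
    for (f in seq_len(n_folds)) {
      val <- ids[fold_of == f]
      ref <- ids[fold_of != f]
      y_ref <- y[ref]
      if (two_comp) {
        ri <- match(ref, rownames(Gf))
        vc <- reml_two(y_ref, Gf[ri, ri], Gr[ri, ri])
        fit <- gfblup_fit(y_ref, Gf, Gr, vc, validation_ids = val)
      } else {
        ri <- match(ref, rownames(G))
        vc <- reml_single(y_ref, G[ri, ri])
        fit <- gblup_fit(y_ref, G, vc, validation_ids = val)
      }
      yv <- y[val]
      gv <- fit$gebv[val]
      acc <- if (sd(yv) == 0 || sd(gv) == 0) NA_real_ else cor(gv, yv)
      rows[[length(rows) + 1]] <- data.frame(
        repeat_i = rep_i, fold = f, size = length(val), accuracy = acc)
    }
  }
  folds <- do.call(rbind, rows)
  ok <- !is.na(folds$accuracy)
  if (!all(ok)) message(sum(!ok), " fold(s) with undefined accuracy excluded")
  structure(list(folds = folds,
                 mean_accuracy = mean(folds$accuracy[ok]),
                 se = sd(folds$accuracy[ok]) / sqrt(sum(ok)),
                 n_folds = n_folds, n_repeats = n_repeats, seed = seed,
                 scenario = scenario),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("CV accuracy%s: %.3f (se %.3f) over %d rounds (%d-fold x %d)\n",
              if (!is.na(x$scenario)) paste0(" [", x$scenario, "]") else "",
              x$mean_accuracy, x$se, nrow(x$folds), x$n_folds, x$n_repeats))
  invisible(x)
}
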