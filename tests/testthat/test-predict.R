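# independent oracle: solve Henderson's mixed model equations directly
mme_solve <- function(y, G, sg2, se2) {
  n <- length(y)
  X <- matrix(1, n, 1)
  Gi <- solve(G)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + Gi * se2 / sg2))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(lhs, rhs)
  list(mu = unname(sol[1]), g = unname(sol[-1]))
}

test_that("GBLUP matches the hand-solved mixed model equations on 3 individuals", {
  G <- matrix(c(1.0, 0.5, 0.25,
                0.5, 1.0, 0.5,
                0.25, 0.5, 1.0), 3, 3)
  dimnames(G) <- list(c("a", "b", "c"), c("a", "b", "c"))
  y <- c(a = 1.2, b = -0.4, c = 0.7)
  vc <- list(sigma_g2 = 1, sigma_e2 = 1)
  fit <- gblup_fit(y, G, vc)
  ref <- mme_solve(y, G, 1, 1)
  expect_equal(fit$mu, ref$mu, tolerance = 1e-10)
  expect_equal(unname(fit$gebv), unname(ref$g), tolerance = 1e-10)
})

test_that("prediction of unphenotyped animals equals the MME with missing records", {
  set.seed(51)
  gm <- hwe_geno(n = 60, m = 300, seed = 51)
  G <- vanraden_grm(gm)
  tr <- sim_trait(gm, h2 = 0.5, seed = 51)
  val <- rownames(gm$geno)[41:60]
  ref_ids <- rownames(gm$geno)[1:40]
  vc <- reml_single(tr$y[ref_ids], unclass(G)[ref_ids, ref_ids])
  fit <- gblup_fit(tr$y[ref_ids], G, vc, validation_ids = val)
  # oracle: conditional expectation from joint normality, computed with
  # plain solve() on the reference block
  Vrr <- vc$sigma_g2 * unclass(G)[ref_ids, ref_ids] +
    diag(vc$sigma_e2, 40)
  mu <- drop(solve(sum(solve(Vrr)),
                   sum(solve(Vrr) %*% tr$y[ref_ids])))
  gv <- vc$sigma_g2 * unclass(G)[val, ref_ids] %*%
    solve(Vrr, tr$y[ref_ids] - mu)
  expect_equal(fit$gebv[val], drop(gv), tolerance = 1e-8)
  expect_true(all(!is.na(fit$gebv)))
})

test_that("GEBV approach the centered phenotypes as residual variance vanishes", {
  set.seed(52)
  gm <- hwe_geno(n = 50, m = 400, seed = 52)
  G <- unclass(vanraden_grm(gm)) + diag(1e-4, 50)   # full rank
  dimnames(G) <- list(rownames(gm$geno), rownames(gm$geno))
  y <- sim_trait(gm, h2 = 0.9, seed = 52)$y
  fit <- gblup_fit(y, G, list(sigma_g2 = 1, sigma_e2 = 1e-10))
  expect_equal(unname(fit$gebv[names(y)]), unname(y - fit$mu),
               tolerance = 1e-4)
})

test_that("GEBV are shrunken and linear in the phenotypes", {
  gm <- hwe_geno(n = 80, m = 300, seed = 53)
  G <- vanraden_grm(gm)
  tr <- sim_trait(gm, h2 = 0.4, seed = 53)
  vc <- reml_single(tr$y, G)
  fit <- gblup_fit(tr$y, G, vc)
  expect_lte(var(fit$gebv[names(tr$y)]), var(tr$y - fit$mu))
  # doubling centered phenotypes doubles the GEBV (components held fixed)
  y2 <- 2 * (tr$y - mean(tr$y)) + mean(tr$y)
  fit2 <- gblup_fit(y2, G, vc)
  expect_equal(unname(fit2$gebv), 2 * unname(fit$gebv), tolerance = 1e-8)
})

test_that("GRM-based GBLUP equals marker-effect ridge regression (SNP-BLUP)", {
  set.seed(54)
  gm <- hwe_geno(n = 50, m = 200, seed = 54)
  g <- gm$geno
  p <- colMeans(g) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(g[, poly], 2, 2 * p[poly])
  c2pq <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- vanraden_grm(gm)
  tr <- sim_trait(gm, h2 = 0.5, seed = 54)
  vc <- reml_single(tr$y, G)
  fit <- gblup_fit(tr$y, G, vc)
  # ridge regression of marker effects u ~ N(0, sg2/c2pq I):
  # u_hat = Z' (Z Z' + c2pq * delta I)^-1 (y - mu); gebv = Z u_hat
  lam <- c2pq * vc$sigma_e2 / vc$sigma_g2
  u <- crossprod(Z, solve(tcrossprod(Z) + diag(lam, 50),
                          tr$y - fit$mu))
  expect_equal(unname(fit$gebv), unname(drop(Z %*% u)), tolerance = 1e-6)
})

test_that("GFBLUP reduces to GBLUP at the lambda boundaries", {
  gm <- hwe_geno(n = 70, m = 400, seed = 55)
  Gf <- vanraden_grm(subset_genotypes(gm, variants = 1:200))
  Gr <- vanraden_grm(subset_genotypes(gm, variants = 201:400))
  tr <- sim_trait(gm, h2 = 0.4, seed = 55)
  vc0 <- list(sigma_f2 = 0.0, sigma_r2 = 0.5, sigma_e2 = 0.5,
              identifiable = TRUE)
  f0 <- gfblup_fit(tr$y, Gf, Gr, vc0)
  g0 <- gblup_fit(tr$y, Gr, list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_equal(f0$gebv, g0$gebv, tolerance = 1e-10)
  vc1 <- list(sigma_f2 = 0.5, sigma_r2 = 0.0, sigma_e2 = 0.5,
              identifiable = TRUE)
  f1 <- gfblup_fit(tr$y, Gf, Gr, vc1)
  g1 <- gblup_fit(tr$y, Gf, list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_equal(f1$gebv, g1$gebv, tolerance = 1e-10)
  # identical Gf = Gr with any lambda is exactly GBLUP on that matrix
  vc5 <- list(sigma_f2 = 0.3, sigma_r2 = 0.2, sigma_e2 = 0.5,
              identifiable = TRUE)
  f5 <- gfblup_fit(tr$y, Gf, Gf, vc5)
  g5 <- gblup_fit(tr$y, Gf, list(sigma_g2 = 0.5, sigma_e2 = 0.5))
  expect_equal(f5$gebv, g5$gebv, tolerance = 1e-10)
  # a non-identifiable variance fit aborts the scenario
  expect_error(gfblup_fit(tr$y, Gf, Gr, list(identifiable = FALSE)),
               "not identifiable")
})

test_that("cross-validation partitions correctly and is reproducible", {
  gm <- hwe_geno(n = 100, m = 400, seed = 56)
  G <- vanraden_grm(gm)
  tr <- sim_trait(gm, h2 = 0.5, seed = 56)
  cv <- crossvalidate(tr$y, G = G, n_folds = 5, n_repeats = 2, seed = 9)
  expect_equal(nrow(cv$folds), 10)
  # fold sizes differ by at most 1 and cover everyone once per repeat
  for (r in 1:2) {
    sz <- cv$folds$size[cv$folds$repeat_i == r]
    expect_lte(max(sz) - min(sz), 1)
    expect_equal(sum(sz), 100)
  }
  expect_true(all(cv$folds$accuracy >= -1 & cv$folds$accuracy <= 1))
  cv2 <- crossvalidate(tr$y, G = G, n_folds = 5, n_repeats = 2, seed = 9)
  expect_identical(cv$folds, cv2$folds)
})

test_that("accuracy approaches 1 when phenotypes are noiseless breeding values", {
  # marker count below the training-fold size, QTL inside the marker set:
  # with no residual noise the marker effects are exactly recoverable
  set.seed(57)
  gm <- hwe_geno(n = 150, m = 80, seed = 57)
  G <- vanraden_grm(gm)
  tr <- sim_trait(gm, h2 = 1, n_qtl = 40, seed = 57)
  cv <- crossvalidate(tr$y, G = G, n_folds = 5, seed = 3)
  expect_gt(cv$mean_accuracy, 0.98)
})
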