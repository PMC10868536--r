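#' Single-component REML via the profiled eigendecomposition likelihood
#'
#' Fits `y = X b + g + e` with `var(g) = G sigma_g2`, `var(e) = I
#' sigma_e2` by restricted maximum likelihood. `G` is eigendecomposed
#' once; the restricted likelihood is profiled down to the single ratio
#' `delta = sigma_e2 / sigma_g2` and maximised by a coarse log-grid
#' followed by golden-section refinement, then the components are
#' recovered in closed form.
#'
#' @param y numeric phenotype vector (fixed-effect-corrected).
#' @param G `grm` over the same individuals, in the same order.
#' @param X fixed-effect design matrix; default intercept only.
#' @param delta_range search range for `delta` (log-spaced).
#' @return A `varcomp` object: list with `sigma_g2`, `sigma_e2`, `h2`,
#'   `reml_loglik`, `converged`, `n_iterations`, `model = "single"`.
#' @export
reml_single <- function(y, G, X = NULL,
                        delta_range = c(1e-6, 1e6)) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n)
  if (var(y) == 0) stop("phenotype has zero variance")
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  # standardise internally so the delta profile is invariant to affine
  # phenotype transforms; rounding to 12 significant digits maps affinely
  # equivalent inputs to the identical vector, so the optimiser returns
  # bit-identical components (the perturbation is ~1e-12 relative, far
  # below estimation error); components are rescaled on exit
  y_scale <- sd(y)
  y_center <- mean(y)
  y <- signif((y - y_center) / y_scale, 12)
  ed <- eigen(G, symmetric = TRUE)
  d <- ed$values
  if (min(d) < -1e-8 * max(abs(d)))
    message("GRM not PSD (min eigenvalue ", signif(min(d), 3),
            "); eigenvalues floored at 0")
  d <- pmax(d, 0)
  yt <- crossprod(ed$vectors, y)
  Xt <- crossprod(ed$vectors, X)
  ll_profile <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xt, w * Xt)
    beta <- solve(XtWX, crossprod(Xt, w * yt))
    r <- yt - Xt %*% beta
    rss <- sum(w * r^2)
    -0.5 * ((n - p) * log(rss / (n - p)) + sum(log(d + delta)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1] +
              (n - p) * (1 + log(2 * pi)))
  }
  grid <- seq(log(delta_range[1]), log(delta_range[2]), length.out = 81)
  ll_grid <- vapply(grid, ll_profile, numeric(1))
  i_best <- which.max(ll_grid)
  lo <- grid[max(1, i_best - 1)]; hi <- grid[min(length(grid), i_best + 1)]
  opt <- optimize(ll_profile, c(lo, hi), maximum = TRUE, tol = 1e-10)
  # boundary: if the grid maximum sits at an endpoint, prefer it
  if (ll_grid[i_best] > opt$objective) {
    opt <- list(maximum = grid[i_best], objective = ll_grid[i_best])
  }
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, w * Xt)
  beta <- solve(XtWX, crossprod(Xt, w * yt))
  r <- yt - Xt %*% beta
  sigma_g2 <- sum(w * r^2) / (n - p) * y_scale^2
  sigma_e2 <- delta * sigma_g2
  beta <- drop(beta) * y_scale
  ic <- which(apply(X, 2, function(col) all(col == 1)))[1]
  if (!is.na(ic)) beta[ic] <- beta[ic] + y_center
  structure(list(model = "single", sigma_g2 = sigma_g2,
                 sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 delta = delta, beta = beta,
                 reml_loglik = opt$objective - (n - p) * log(y_scale),
                 n_iterations = NA_integer_, converged = TRUE),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  if (x$model == "single") {
    cat(sprintf("REML (single): sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f, logLik = %.4f\n",
                x$sigma_g2, x$sigma_e2, x$h2, x$reml_loglik))
  } else {
    cat(sprintf(
      "REML (two): sigma_f2 = %.4g, sigma_r2 = %.4g, sigma_e2 = %.4g, lambda = %.3f, h2 = %.3f, logLik = %.4f (%s, %d it)\n",
      x$sigma_f2, x$sigma_r2, x$sigma_e2, x$lambda, x$h2, x$reml_loglik,
      if (x$converged) "converged" else "NOT converged", x$n_iterations))
  }
  invisible(x)
}

# restricted log-likelihood and P matrix for V = sum theta_i K_i
reml_ll_parts <- function(y, X, Vlist, theta) {
  n <- length(y)
  V <- Reduce(`+`, Map(`*`, Vlist, theta))
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  XtViX <- crossprod(X, Vi %*% X)
  XtViX_i <- solve(XtViX)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% XtViX_i %*% t(ViX)
  Py <- P %*% y
  ll <- -0.5 * (logdetV + determinant(XtViX, TRUE)$modulus[1] +
                  sum(y * Py) + (n - ncol(X)) * log(2 * pi))
  list(ll = as.numeric(ll), P = P, Py = Py)
}

#' Two-component REML by average information with EM fallback
#'
#' Fits `y = X b + f + r + e` with `var(f) = Gf sigma_f2`, `var(r) = Gr
#' sigma_r2`, `var(e) = I sigma_e2`. The first iterations use EM-style
#' updates; later iterations take average-information (AI) steps,
#' falling back to EM with step halving whenever an AI step would lower
#' the restricted likelihood or push a component below the variance
#' floor (`1e-8 * var(y)`). Components pinned at the floor are flagged
#' `boundary`. If `Gf` and `Gr` are numerically identical only the sum
#' of the two genetic variances is identifiable and the fit is flagged
#' `identifiable = FALSE` (lambda is `NA`).
#'
#' @param y numeric phenotype vector.
#' @param Gf,Gr feature and residual `grm` matrices, same individuals
#'   and order as `y`.
#' @param X fixed-effect design; default intercept.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @param n_em number of initial EM iterations before AI steps.
#' @return A `varcomp` object with `sigma_f2`, `sigma_r2`, `sigma_e2`,
#'   `lambda`, `h2`, `reml_loglik`, `converged`, `boundary`,
#'   `identifiable`.
#' @export
reml_two <- function(y, Gf, Gr, X = NULL, max_iter = 100L, tol = 1e-8,
                     n_em = 3L) {
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(Gf) == n, nrow(Gr) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  identifiable <- TRUE
  nf <- norm(unclass(Gf) - unclass(Gr), "F")
  if (nf <= 1e-10 * max(norm(unclass(Gf), "F"), 1)) identifiable <- FALSE
  vy <- var(y)
  floor_v <- 1e-8 * vy
  Vlist <- list(unclass(Gf), unclass(Gr), diag(n))
  theta <- c(vy / 4, vy / 4, vy / 2)
  parts <- reml_ll_parts(y, X, Vlist, theta)
  if (is.null(parts)) stop("initial covariance matrix not positive definite")
  ll <- parts$ll
  conv <- FALSE
  it <- 0L
  em_step <- function(theta, parts) {
    Py <- parts$Py
    vapply(seq_along(theta), function(i) {
      tr_PK <- sum(parts$P * Vlist[[i]])   # tr(P K_i), K symmetric
      yPKPy <- as.numeric(crossprod(Py, Vlist[[i]] %*% Py))
      max(theta[i] + theta[i]^2 * (yPKPy - tr_PK) / n, floor_v)
    }, numeric(1))
  }
  ai_step <- function(theta, parts) {
    Py <- parts$Py
    KPy <- lapply(Vlist, function(K) K %*% Py)
    score <- vapply(seq_along(theta), function(i)
      -0.5 * (sum(parts$P * Vlist[[i]]) -
                as.numeric(crossprod(Py, KPy[[i]]))), numeric(1))
    AI <- matrix(0, 3, 3)
    PKPy <- lapply(KPy, function(v) parts$P %*% v)
    for (i in 1:3) for (j in i:3) {
      AI[i, j] <- AI[j, i] <- 0.5 * as.numeric(crossprod(KPy[[i]],
                                                         PKPy[[j]]))
    }
    upd <- tryCatch(solve(AI, score), error = function(e) NULL)
    if (is.null(upd)) return(NULL)
    theta + upd
  }
  while (it < max_iter) {
    it <- it + 1L
    proposal <- if (it > n_em) ai_step(theta, parts) else NULL
    accepted <- FALSE
    if (!is.null(proposal) && all(is.finite(proposal))) {
      prop <- pmax(proposal, floor_v)
      new_parts <- reml_ll_parts(y, X, Vlist, prop)
      if (!is.null(new_parts) && new_parts$ll >= ll - 1e-12) {
        theta_new <- prop; parts_new <- new_parts; accepted <- TRUE
      }
    }
    if (!accepted) {  # EM with step halving; EM never decreases the
                      # restricted likelihood except through the floor
      prop <- em_step(theta, parts)
      new_parts <- reml_ll_parts(y, X, Vlist, prop)
      half <- 0
      while ((is.null(new_parts) || new_parts$ll < ll - 1e-10) &&
             half < 20) {
        prop <- (prop + theta) / 2
        new_parts <- reml_ll_parts(y, X, Vlist, prop)
        half <- half + 1
      }
      if (is.null(new_parts)) break
      theta_new <- prop; parts_new <- new_parts
    }
    dll <- parts_new$ll - ll
    rel <- max(abs(theta_new - theta) / pmax(abs(theta), floor_v))
    theta <- theta_new; parts <- parts_new; ll <- parts$ll
    if (abs(dll) < tol && rel < 1e-6) { conv <- TRUE; break }
  }
  boundary <- theta <= floor_v * (1 + 1e-9)
  lam <- if (!identifiable) NA_real_ else {
    if (theta[1] + theta[2] <= 0) NA_real_ else theta[1] / (theta[1] + theta[2])
  }
  structure(list(model = "two", sigma_f2 = theta[1], sigma_r2 = theta[2],
                 sigma_e2 = theta[3], lambda = lam,
                 h2 = (theta[1] + theta[2]) / sum(theta),
                 reml_loglik = ll, n_iterations = it, converged = conv,
                 boundary = boundary, identifiable = identifiable),
            class = "varcomp")
}

#' Feature weight lambda from variance components
#'
#' `lambda = sigma_f2 / (sigma_f2 + sigma_r2)`: the fraction of additive
#' genetic variance captured by the feature panel, used to collapse the
#' two GRMs into one combined matrix.
#'
#' @param vc a two-component `varcomp` object, or a list with
#'   `sigma_f2` and `sigma_r2`.
#' @return Fraction in `[0, 1]`.
#' @export
compute_lambda <- function(vc) {
  sf <- vc$sigma_f2; sr <- vc$sigma_r2
  if (is.null(sf) || is.null(sr))
    stop("need a two-component fit with sigma_f2 and sigma_r2")
  if (!is.null(vc$identifiable) && !vc$identifiable)
    stop("lambda is not identifiable: the two GRMs are identical")
  if (sf + sr <= 0) stop("no genetic variance: sigma_f2 + sigma_r2 = 0")
  sf / (sf + sr)
}
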