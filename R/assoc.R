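#' Mixed-linear-model association scan (EMMAX-style)
#'
#' Null variance components `(sigma_g2, sigma_e2)` are estimated once by
#' [reml_single()]; every variant is then tested by generalized least
#' squares with the covariance `V = G sigma_g2 + I sigma_e2` held fixed.
#' A single eigendecomposition of `G` whitens the phenotype, intercept
#' and all dosage columns, after which each test is an ordinary weighted
#' regression; the Wald statistic is referred to a 1-df chi-square.
#' Missing dosages are mean-imputed per variant; monomorphic variants
#' are flagged untested rather than dropped.
#'
#' @param y numeric fixed-effect-corrected phenotype.
#' @param geno a [genotype_matrix()] over the same individuals, same
#'   order.
#' @param G `grm` for the polygenic term, same order.
#' @return data.frame of class `gwas_result`: per variant `id`, `chrom`,
#'   `pos`, `ref`, `alt`, `beta`, `se`, `chisq`, `p`, `tested`;
#'   attributes `sigma_g2`, `sigma_e2`, `n`.
#' @export
mlm_gwas <- function(y, geno, G) {
  stopifnot(inherits(geno, "genotype_matrix"))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(geno$geno) == n, nrow(G) == n)
  vc <- reml_single(y, G)
  ed <- eigen(unclass(G), symmetric = TRUE)
  d <- pmax(ed$values, 0)
  w <- 1 / (vc$sigma_g2 * d + vc$sigma_e2)   # precision weights
  U <- ed$vectors
  yt <- drop(crossprod(U, y))
  ones <- drop(crossprod(U, rep(1, n)))
  g <- geno$geno
  mono <- apply(g, 2, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) < 2
  })
  if (anyNA(g)) {
    mu <- colMeans(g, na.rm = TRUE)
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- mu[idx[, 2]]
  }
  Xt <- crossprod(U, g)                      # rotated dosages
  # per-variant GLS with covariates (1, x): closed form 2x2 solve
  s11 <- sum(w * ones^2)
  s1y <- sum(w * ones * yt)
  s1x <- colSums(w * ones * Xt)
  sxx <- colSums(w * Xt^2)
  sxy <- colSums(w * Xt * yt)
  det2 <- s11 * sxx - s1x^2
  beta <- (s11 * sxy - s1x * s1y) / det2
  var_beta <- s11 / det2
  chisq <- beta^2 / var_beta
  p <- pchisq(chisq, df = 1, lower.tail = FALSE)
  beta[mono] <- NA; var_beta[mono] <- NA; chisq[mono] <- NA; p[mono] <- NA
  out <- data.frame(id = geno$variants$id, chrom = geno$variants$chrom,
                    pos = geno$variants$pos, ref = geno$variants$ref,
                    alt = geno$variants$alt,
                    beta = beta, se = sqrt(var_beta), chisq = chisq,
                    p = p, tested = !mono, stringsAsFactors = FALSE)
  attr(out, "sigma_g2") <- vc$sigma_g2
  attr(out, "sigma_e2") <- vc$sigma_e2
  attr(out, "n") <- n
  class(out) <- c("gwas_result", "data.frame")
  out
}

#' Genomic inflation factor
#'
#' `lambda_GC = median(chisq) / qchisq(0.5, 1)`; near 1 for a
#' well-calibrated scan.
#'
#' @param gwas a [mlm_gwas()] result or numeric chi-square vector.
#' @return Numeric inflation factor.
#' @export
genomic_inflation <- function(gwas) {
  x <- if (is.data.frame(gwas)) gwas$chisq[gwas$tested] else gwas
  median(x, na.rm = TRUE) / stats::qchisq(0.5, df = 1)
}

#' Study-specific FDR significance threshold
#'
#' `threshold = fdr * N / M` where `N` is the number of tested variants
#' with p < 0.05 and `M` the total number of tested variants. This is
#' the preselection rule used for trait-associated SNP panels; it is
#' deliberately not Benjamini-Hochberg (see `method = "bh"` for the
#' standard alternative).
#'
#' @param pvals numeric p-values (`NA` for untested variants allowed).
#' @param fdr nominal false discovery rate, default 0.05.
#' @param method `"nm"` for the N/M rule (default) or `"bh"` for the
#'   largest Benjamini-Hochberg-rejected p-value.
#' @return Significance threshold on the p-value scale.
#' @export
fdr_threshold <- function(pvals, fdr = 0.05, method = c("nm", "bh")) {
  method <- match.arg(method)
  pvals <- pvals[!is.na(pvals)]
  if (!length(pvals)) stop("no p-values supplied")
  stopifnot(fdr > 0, fdr < 1)
  if (method == "nm") {
    N <- sum(pvals < 0.05)
    M <- length(pvals)
    return(fdr * N / M)
  }
  # BH: largest p with p_(k) <= k/M * fdr
  ps <- sort(pvals)
  M <- length(ps)
  ok <- which(ps <= seq_len(M) / M * fdr)
  if (!length(ok)) 0 else ps[max(ok)]
}

#' Select significant variants into a panel
#'
#' Variants with `p < threshold`, ordered by `(chrom, pos)`.
#'
#' @param gwas a [mlm_gwas()] result.
#' @param threshold p-value threshold in `[0, 1]`.
#' @param discovery optional label recording the discovery population.
#' @param trait optional trait label.
#' @return A [panel_spec()] (possibly empty).
#' @export
select_significant <- function(gwas, threshold, discovery = NA, trait = NA) {
  stopifnot(threshold >= 0, threshold <= 1)
  hit <- gwas[!is.na(gwas$p) & gwas$p < threshold, , drop = FALSE]
  hit <- hit[order(hit$chrom, hit$pos), , drop = FALSE]
  panel_spec(paste0("gwas", if (!is.na(trait)) paste0("_", trait)),
             hit$id,
             provenance = list(source = "gwas", discovery = discovery,
                               trait = trait, threshold = threshold))
}
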