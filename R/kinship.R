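#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: `G = Z Z' / (2 * sum_j p_j (1 - p_j))` where column `j`
#' of `Z` is the dosage minus `2 p_j`, and `p_j` is the observed
#' alternate-allele frequency in the analysis sample. Missing genotypes
#' are replaced by `2 p_j` (i.e. contribute 0 after centering).
#' Monomorphic variants contribute nothing to the denominator; if all
#' variants are monomorphic the GRM is undefined.
#'
#' @param geno a [genotype_matrix()] or dosage matrix (individuals x
#'   variants).
#' @return A `grm` object: a symmetric numeric matrix with individual ids
#'   as dimnames and attributes `n_markers` and `af_source`.
#' @export
vanraden_grm <- function(geno) {
  g <- if (inherits(geno, "genotype_matrix")) geno$geno else as.matrix(geno)
  if (nrow(g) < 2) stop("need at least 2 individuals")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("all variants monomorphic: VanRaden denominator is zero")
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  Z <- sweep(g, 2, 2 * p)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  structure(G, n_markers = sum(poly), af_source = "observed",
            class = c("grm", class(G)))
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("GRM: %d individuals, %d markers, mean diagonal %.3f\n",
              nrow(x), attr(x, "n_markers"), mean(diag(x))))
  invisible(x)
}

#' Identity-by-state similarity matrix
#'
#' Entry `(i, k)` is the mean over shared non-missing variants of
#' `(2 - |g_i - g_k|) / 2`: 1 for identical genotypes, 0 for opposite
#' homozygotes. Diagonal is 1.
#'
#' @inheritParams vanraden_grm
#' @return A `grm`-shaped similarity matrix. Pairs with no shared
#'   non-missing variant are `NA` and counted in the `n_undefined`
#'   attribute.
#' @export
ibs_matrix <- function(geno) {
  g <- if (inherits(geno, "genotype_matrix")) geno$geno else as.matrix(geno)
  if (nrow(g) < 2) stop("need at least 2 individuals")
  obs <- !is.na(g)
  g0 <- g; g0[!obs] <- 0
  # sum |gi - gk| over shared sites: |a-b| for a,b in 0..2 decomposes as
  # sum over the two haplotype-dosage indicators I(g>=1) and I(g==2)
  a1 <- (g0 >= 1) * obs; a2 <- (g0 == 2) * obs
  shared <- tcrossprod(obs * 1)
  # |gi-gk| = |I(gi>=1)-I(gk>=1)| + |I(gi==2)-I(gk==2)| for gi,gk in 0:2
  d1 <- outer_mismatch(a1, obs)
  d2 <- outer_mismatch(a2, obs)
  ibs <- 1 - (d1 + d2) / (2 * shared)
  ibs[shared == 0] <- NA
  diag(ibs) <- 1
  structure(ibs, n_markers = ncol(g), n_undefined = sum(shared == 0),
            af_source = "none", class = c("grm", class(ibs)))
}

# sum over shared sites of |x_i - x_k| for 0/1 matrices x masked by obs:
# |xi-xk| = xi(1-xk) + xk(1-xi), restricted to mutually observed sites
outer_mismatch <- function(x, obs) {
  xo <- x; oo <- obs * 1
  xo %*% t(oo - xo) + (oo - xo) %*% t(xo)
}

#' Combine feature and residual GRMs with weight lambda
#'
#' `G_Total = lambda * G_f + (1 - lambda) * G_r`, entrywise. Both
#' matrices must carry the same individuals in the same order.
#'
#' @param Gf,Gr `grm` matrices over identical individuals.
#' @param lam weight in `[0, 1]`, normally the feature fraction of
#'   genetic variance `sigma_f2 / (sigma_f2 + sigma_r2)`.
#' @return Combined `grm`.
#' @export
combine_grm <- function(Gf, Gr, lam) {
  stopifnot(is.matrix(Gf), is.matrix(Gr), lam >= 0, lam <= 1)
  if (!identical(dim(Gf), dim(Gr)))
    stop("GRM dimensions differ: ", nrow(Gf), " vs ", nrow(Gr))
  if (!is.null(rownames(Gf)) && !is.null(rownames(Gr)) &&
      !identical(rownames(Gf), rownames(Gr))) {
    first <- which(rownames(Gf) != rownames(Gr))[1]
    stop("GRM individual order differs, first mismatch at position ", first,
         ": '", rownames(Gf)[first], "' vs '", rownames(Gr)[first], "'")
  }
  G <- lam * Gf + (1 - lam) * Gr
  structure(as.matrix(G),
            n_markers = sum(attr(Gf, "n_markers"), attr(Gr, "n_markers")),
            af_source = "combined", lambda = lam,
            class = c("grm", "matrix", "array"))
}

#' Binned LD decay from genotype dosages
#'
#' For every intra-chromosomal variant pair within `max_dist`, r2 is the
#' squared Pearson correlation of dosages (composite LD, the standard
#' unphased-data surrogate); pairs are binned by physical distance.
#' Monomorphic variants are excluded (r2 undefined).
#'
#' @param geno a [genotype_matrix()].
#' @param max_dist maximum pair distance in bp.
#' @param bin_width distance bin width in bp.
#' @return data.frame of class `ld_decay`: `bin_start`, `bin_end`,
#'   `mean_r2`, `n_pairs`; attribute `n_monomorphic` counts skipped
#'   variants.
#' @export
ld_decay <- function(geno, max_dist = 500000, bin_width = 10000) {
  stopifnot(inherits(geno, "genotype_matrix"))
  v <- geno$variants
  ord <- order(v$chrom, v$pos)
  v <- v[ord, ]
  g <- geno$geno[, ord, drop = FALSE]
  sds <- apply(g, 2, sd, na.rm = TRUE)
  poly <- !is.na(sds) & sds > 0
  n_mono <- sum(!poly)
  v <- v[poly, ]; g <- g[, poly, drop = FALSE]
  edges <- seq(0, max_dist, by = bin_width)
  if (edges[length(edges)] < max_dist) edges <- c(edges, max_dist)
  nb <- length(edges) - 1
  sum_r2 <- cnt <- numeric(nb)
  for (ch in unique(v$chrom)) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2) next
    pos <- v$pos[idx]
    gg <- g[, idx, drop = FALSE]
    for (i in seq_len(length(idx) - 1)) {
      dist <- pos[(i + 1):length(idx)] - pos[i]
      within <- which(dist <= max_dist)
      if (!length(within)) next
      j <- i + within
      r <- suppressWarnings(
        cor(gg[, i], gg[, j, drop = FALSE],
            use = "pairwise.complete.obs"))
      r2 <- as.numeric(r)^2
      b <- pmin(pmax(ceiling(dist[within] / bin_width), 1), nb)
      ok <- !is.na(r2)
      if (any(ok)) {
        tb <- tapply(r2[ok], b[ok], sum)
        bi <- as.integer(names(tb))
        sum_r2[bi] <- sum_r2[bi] + tb
        tn <- tapply(rep(1, sum(ok)), b[ok], sum)
        cnt[bi] <- cnt[bi] + tn
      }
    }
  }
  out <- data.frame(bin_start = edges[-length(edges)],
                    bin_end = edges[-1],
                    mean_r2 = ifelse(cnt > 0, sum_r2 / cnt, NA_real_),
                    n_pairs = cnt)
  attr(out, "n_monomorphic") <- n_mono
  class(out) <- c("ld_decay", "data.frame")
  out
}

#' Pairwise r2 between two dosage vectors
#'
#' @param x,y numeric dosage vectors.
#' @return Squared Pearson correlation over pairwise-complete entries.
#' @export
pair_r2 <- function(x, y) {
  suppressWarnings(cor(x, y, use = "pairwise.complete.obs")^2)
}
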