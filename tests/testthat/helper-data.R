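# shared fixtures, built once per test run and cached

.fixture_env <- new.env(parent = emptyenv())

# medium two-population dataset reused across modules
shared_ds <- function() {
  if (is.null(.fixture_env$ds)) {
    cfg <- sim_config(seed = 42, n_individuals = c(val = 300, disc = 150),
                      n_variants_dense = 4000, n_variants_chip = 800,
                      n_genes = 40)
    .fixture_env$ds <- simulate_dataset(cfg)
  }
  .fixture_env$ds
}

# tiny hand-built genotype matrix
toy_geno <- function(g, chrom = NULL, pos = NULL) {
  m <- ncol(g)
  if (is.null(chrom)) chrom <- rep("chr1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  variants <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                         pos = pos, ref = "A", alt = "G",
                         stringsAsFactors = FALSE)
  if (is.null(rownames(g))) rownames(g) <- paste0("i", seq_len(nrow(g)))
  genotype_matrix(g, variants)
}

# single-population unstructured genotypes in HWE, no missingness
hwe_geno <- function(n, m, seed = 1) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(g) <- sprintf("ind%04d", seq_len(n))
  toy_geno(g)
}

# phenotype from a genotype matrix with given h2; returns list(y, tbv)
sim_trait <- function(geno, h2, n_qtl = 50, seed = 1, qtl_idx = NULL) {
  set.seed(seed)
  g <- if (inherits(geno, "genotype_matrix")) geno$geno else geno
  if (is.null(qtl_idx)) qtl_idx <- sample.int(ncol(g), n_qtl)
  beta <- rnorm(length(qtl_idx), 0, sqrt(1 / length(qtl_idx)))
  Z <- scale(g[, qtl_idx, drop = FALSE], center = TRUE, scale = FALSE)
  tbv <- drop(Z %*% beta)
  e <- if (h2 >= 1) rep(0, nrow(g)) else
    rnorm(nrow(g), 0, sqrt(max(var(tbv), 1e-12) * (1 - h2) / max(h2, 1e-12)))
  y <- tbv + e
  names(y) <- rownames(g)
  list(y = y, tbv = tbv, qtl = qtl_idx)
}
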