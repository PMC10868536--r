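#' Genotype QC thresholds
#'
#' Threshold container for the quality-control stage. Inequalities are
#' strict: an individual or variant must exceed the call-rate and MAF
#' thresholds, and its Hardy-Weinberg p-value must exceed `min_hwe_p`, to
#' be retained.
#'
#' @param min_individual_call_rate fraction, default 0.90.
#' @param min_variant_call_rate fraction, default 0.90.
#' @param min_maf minor-allele-frequency threshold, default 0.05.
#' @param min_hwe_p exact-test p-value threshold, default 1e-6.
#' @param autosomes_only drop variants on non-autosomal chromosomes
#'   (names matching `X`, `Y`, `MT`, `chrX`, ...), default `TRUE`.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_individual_call_rate = 0.90,
                          min_variant_call_rate = 0.90,
                          min_maf = 0.05,
                          min_hwe_p = 1e-6,
                          autosomes_only = TRUE) {
  fr <- c(min_individual_call_rate, min_variant_call_rate, min_maf)
  stopifnot(all(fr >= 0 & fr <= 1), min_hwe_p >= 0, min_hwe_p <= 1)
  structure(list(min_individual_call_rate = min_individual_call_rate,
                 min_variant_call_rate = min_variant_call_rate,
                 min_maf = min_maf, min_hwe_p = min_hwe_p,
                 autosomes_only = autosomes_only),
            class = "qc_thresholds")
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic variant's genotype counts,
#' computed by the heterozygote-count recurrence over the hypergeometric
#' null conditioned on the observed allele counts (Wigginton-style, no
#' mid-p correction). The p-value is the sum of probabilities of all
#' heterozygote counts no more probable than the observed one.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return p-value in (0, 1]. Monomorphic variants give exactly 1.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("no genotyped individuals at this variant")
  n_rare <- 2 * min(n_AA, n_aa) + n_Aa       # minor allele count
  if (n_rare == 0) return(1)
  # probabilities over all possible heterozygote counts with the same
  # allele totals; het count has the parity of n_rare
  het_lo <- if (n_rare %% 2 == 0) 0L else 1L
  hets <- seq.int(het_lo, n_rare, by = 2L)
  prob <- numeric(length(hets))
  # start from mid-range het count, recur both ways for stability
  mid <- n_rare * (2 * n - n_rare) / (2 * n)
  start <- hets[which.min(abs(hets - mid))]
  i0 <- match(start, hets)
  prob[i0] <- 1
  # P(h-2)/P(h) = h(h-1) / ((hom_r+1)(hom_c+1)*4); with h hets,
  # hom_r = (n_rare - h)/2 rare homozygotes, hom_c = n - h - hom_r.
  if (i0 > 1) for (i in seq(i0 - 1, 1)) {
    h <- hets[i + 1]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    prob[i] <- prob[i + 1] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
  }
  if (i0 < length(hets)) for (i in seq(i0 + 1, length(hets))) {
    h <- hets[i - 1]
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    prob[i] <- prob[i - 1] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
  }
  prob <- prob / sum(prob)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs + 1e-12 * p_obs]))
}

#' Per-variant Hardy-Weinberg p-values
#'
#' @param x a [genotype_matrix()] or dosage matrix.
#' @return Numeric vector of exact-test p-values (`NA` for all-missing
#'   variants).
#' @export
hwe_pvalues <- function(x) {
  g <- if (inherits(x, "genotype_matrix")) x$geno else x
  apply(g, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    hwe_exact_test(sum(col == 0), sum(col == 1), sum(col == 2))
  })
}

is_autosome <- function(chrom) {
  !grepl("^(chr)?(x|y|mt|m|w|z)$", tolower(as.character(chrom)))
}

#' Filter individuals on call rate
#'
#' Retains individuals whose non-missing genotype fraction is strictly
#' greater than `thr$min_individual_call_rate`; order preserved.
#'
#' @param geno a [genotype_matrix()].
#' @param thr a [qc_thresholds()].
#' @return Filtered `genotype_matrix`.
#' @export
filter_individuals <- function(geno, thr = qc_thresholds()) {
  stopifnot(inherits(geno, "genotype_matrix"))
  cr <- rowMeans(!is.na(geno$geno))
  keep <- cr > thr$min_individual_call_rate
  if (!any(keep)) stop("no individuals pass the call-rate filter")
  subset_genotypes(geno, individuals = which(keep))
}

#' Filter variants on call rate, MAF, HWE and chromosome
#'
#' Retains variants passing, in order: autosome membership (if
#' `thr$autosomes_only`), call rate, MAF computed on non-missing
#' genotypes, and the exact Hardy-Weinberg test. All inequalities strict.
#' HWE is tested within each population and a variant fails if it fails
#' in any population (`hwe_scope = "per_population"`), or on the pooled
#' sample (`"pooled"`).
#'
#' @inheritParams filter_individuals
#' @param hwe_scope `"per_population"` (default) or `"pooled"`.
#' @return Filtered `genotype_matrix` with a `qc_report` attribute: a
#'   data.frame of per-variant pass/fail flags, MAF and HWE p.
#' @export
filter_variants <- function(geno, thr = qc_thresholds(),
                            hwe_scope = c("per_population", "pooled")) {
  stopifnot(inherits(geno, "genotype_matrix"))
  hwe_scope <- match.arg(hwe_scope)
  g <- geno$geno
  auto_ok <- if (thr$autosomes_only) is_autosome(geno$variants$chrom)
             else rep(TRUE, ncol(g))
  cr <- colMeans(!is.na(g))
  cr_ok <- cr > thr$min_variant_call_rate
  maf <- minor_allele_freq(g)
  maf_ok <- !is.na(maf) & maf > thr$min_maf
  pops <- geno$samples$population
  if (hwe_scope == "per_population" && !is.null(pops) &&
      length(unique(pops)) > 1) {
    pmat <- sapply(unique(pops), function(pp)
      hwe_pvalues(g[pops == pp, , drop = FALSE]))
    hwe_p <- apply(pmat, 1, min, na.rm = TRUE)
  } else {
    hwe_p <- hwe_pvalues(g)
  }
  hwe_ok <- !is.na(hwe_p) & hwe_p > thr$min_hwe_p
  keep <- auto_ok & cr_ok & maf_ok & hwe_ok
  report <- data.frame(id = geno$variants$id, call_rate = cr, maf = maf,
                       hwe_p = hwe_p, autosome_pass = auto_ok,
                       call_rate_pass = cr_ok, maf_pass = maf_ok,
                       hwe_pass = hwe_ok, pass = keep,
                       stringsAsFactors = FALSE)
  if (!any(keep)) stop("no variants pass QC")
  out <- subset_genotypes(geno, variants = which(keep))
  attr(out, "qc_report") <- report
  out
}

#' Full QC pipeline: individuals, then variants
#'
#' @inheritParams filter_variants
#' @return Filtered `genotype_matrix` (with `qc_report` attribute).
#' @export
qc_genotypes <- function(geno, thr = qc_thresholds(),
                         hwe_scope = c("per_population", "pooled")) {
  filter_variants(filter_individuals(geno, thr), thr, match.arg(hwe_scope))
}
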