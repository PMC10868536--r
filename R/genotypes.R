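#' Genotype matrix container
#'
#' Bundles an individuals x variants dosage matrix (0/1/2 copies of the
#' alternate allele, `NA` for missing) with variant metadata (chromosome,
#' position, ref, alt) and sample metadata (population, sex).
#'
#' @param geno integer/numeric matrix, individuals in rows, variants in
#'   columns. Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per column of `geno`, in order.
#' @param samples data.frame with columns `id` and optionally `population`,
#'   `sex`; one row per row of `geno`, in order.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, variants, samples = NULL) {
  geno <- as.matrix(geno)
  stopifnot(is.data.frame(variants), ncol(geno) == nrow(variants))
  req <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(variants))
  if (length(miss)) stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(variants$id)) stop("variant ids must be unique")
  if (is.null(samples)) {
    ids <- rownames(geno)
    if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(geno)))
    samples <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(geno) == nrow(samples))
  bad <- geno[!is.na(geno) & !(geno %in% 0:2)]
  if (length(bad)) stop("genotype dosages must be 0, 1, 2 or NA")
  rownames(geno) <- samples$id
  colnames(geno) <- variants$id
  structure(list(geno = geno, variants = as.data.frame(variants),
                 samples = as.data.frame(samples)),
            class = "genotype_matrix")
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants\n",
              nrow(x$geno), ncol(x$geno)))
  if (!is.null(x$samples$population))
    cat("populations:", paste(names(table(x$samples$population)),
                              table(x$samples$population), collapse = ", "), "\n")
  nm <- sum(is.na(x$geno))
  cat(sprintf("missing: %.3f%%\n", 100 * nm / length(x$geno)))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param individuals logical/integer/character index of rows to keep.
#' @param variants logical/integer/character index of variant columns to keep.
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_genotypes <- function(x, individuals = NULL, variants = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- x$geno; vt <- x$variants; sm <- x$samples
  if (!is.null(individuals)) {
    if (is.character(individuals)) individuals <- match(individuals, sm$id)
    g <- g[individuals, , drop = FALSE]; sm <- sm[individuals, , drop = FALSE]
  }
  if (!is.null(variants)) {
    if (is.character(variants)) variants <- match(variants, vt$id)
    g <- g[, variants, drop = FALSE]; vt <- vt[variants, , drop = FALSE]
  }
  genotype_matrix(g, vt, sm)
}

#' Canonical variant identity key
#'
#' Variant identity is `(chrom, pos, ref, alt)`; positions alone collide at
#' multiallelic sites.
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Write genotypes to a VCF v4.2 file
#'
#' Plain-text VCF with a single `GT` FORMAT field; missing genotypes are
#' written as `./.`.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  v <- x$variants
  gt <- matrix("./.", nrow(x$geno), ncol(x$geno))
  gt[!is.na(x$geno) & x$geno == 0] <- "0/0"
  gt[!is.na(x$geno) & x$geno == 1] <- "0/1"
  gt[!is.na(x$geno) & x$geno == 2] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples$id), collapse = "\t"))
  body <- data.table::data.table(
    CHROM = v$chrom, POS = v$pos, ID = v$id, REF = v$ref, ALT = v$alt,
    QUAL = ".", FILTER = "PASS", INFO = ".", FORMAT = "GT")
  body <- cbind(body, data.table::as.data.table(t(gt)))
  writeLines(header, path)
  data.table::fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Reads a diploid biallelic VCF (via vcfR) into a [genotype_matrix()].
#' Multiallelic records are dropped with a message.
#'
#' @param path VCF file path.
#' @param samples optional sample metadata data.frame with an `id` column;
#'   matched to VCF sample names.
#' @return A `genotype_matrix`.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  keep <- !grepl(",", fix$ALT, fixed = TRUE)
  if (!all(keep)) {
    message(sum(!keep), " multiallelic record(s) dropped")
    v <- v[keep, ]
    fix <- fix[keep, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos[clean %in% c("0/0")] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean %in% c("1/1")] <- 2L
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    blank <- is.na(ids) | ids == "."
    ids[blank] <- paste(fix$CHROM[blank], fix$POS[blank], sep = "_")
  }
  variants <- data.frame(id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         stringsAsFactors = FALSE)
  geno <- t(dos)
  rownames(geno) <- colnames(gt)
  if (is.null(samples)) {
    samples <- data.frame(id = colnames(gt), stringsAsFactors = FALSE)
  } else {
    samples <- samples[match(colnames(gt), samples$id), , drop = FALSE]
  }
  genotype_matrix(geno, variants, samples)
}

#' Alternate-allele frequencies
#'
#' @param x a [genotype_matrix()] or dosage matrix.
#' @return Numeric vector of per-variant alternate-allele frequencies
#'   computed on non-missing genotypes.
#' @export
allele_freq <- function(x) {
  g <- if (inherits(x, "genotype_matrix")) x$geno else x
  colMeans(g, na.rm = TRUE) / 2
}

#' Minor allele frequencies
#'
#' @inheritParams allele_freq
#' @return Numeric vector: `pmin(p, 1 - p)` of the alternate-allele
#'   frequency. Symmetric under ref/alt relabelling.
#' @export
minor_allele_freq <- function(x) {
  p <- allele_freq(x)
  pmin(p, 1 - p)
}
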