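#' Simulation configuration
#'
#' Parameters of the synthetic two-population genotype/phenotype generator.
#' Defaults emulate the study design the package targets: a large
#' validation population and a small discovery population genotyped at
#' sequence density with a chip-density subset, LD decaying over tens of
#' kb, six growth traits with moderate heritability, and optional
#' enrichment of QTL in one genomic class.
#'
#' @param seed integer RNG seed; identical configs give bit-identical
#'   output.
#' @param n_chromosomes number of autosomes.
#' @param chrom_length_bp chromosome length in bp.
#' @param n_genes number of genes placed on the genome (0 allowed).
#' @param n_variants_dense sequence-density variant count (genome-wide).
#' @param n_variants_chip chip-density subset size; must not exceed
#'   `n_variants_dense`.
#' @param n_individuals named integer vector, individuals per population,
#'   e.g. `c(val = 1000, disc = 250)`.
#' @param fst Wright's fixation index driving between-population allele
#'   frequency divergence (Balding-Nichols); in `[0, 1)`.
#' @param h2_target narrow-sense heritability of each simulated trait;
#'   scalar or named per trait.
#' @param n_qtl number of causal variants per trait.
#' @param qtl_class genomic class QTL are enriched in, or `"uniform"`.
#' @param qtl_class_fraction fraction of QTL forced into `qtl_class`.
#' @param ld_block_bp mean haplotype-block length controlling LD decay;
#'   0 disables LD.
#' @param n_founder_haplotypes size of the per-population founder
#'   haplotype pool the mosaics copy from; smaller pools give stronger
#'   baseline LD. The default of 4 reproduces the strong short-range LD
#'   (r2 around 0.3 below 10 kb) of intensively selected livestock
#'   populations with small effective size.
#' @param trait_set names of simulated traits.
#' @param sex_ratio probability an individual is sire-line (`"sire"`).
#' @param missing_rate fraction of genotype calls set to missing.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L,
                       chrom_length_bp = 3e6L,
                       n_genes = 60L,
                       n_variants_dense = 20000L,
                       n_variants_chip = 3000L,
                       n_individuals = c(val = 1000L, disc = 250L),
                       fst = 0.10,
                       h2_target = 0.30,
                       n_qtl = 100L,
                       qtl_class = "uniform",
                       qtl_class_fraction = 1,
                       ld_block_bp = 50000L,
                       n_founder_haplotypes = 4L,
                       trait_set = c("ADG", "AGE", "BF", "LMA", "LMD", "LMP"),
                       sex_ratio = 0.5,
                       missing_rate = 0.01) {
  stopifnot(n_variants_chip <= n_variants_dense,
            qtl_class_fraction >= 0, qtl_class_fraction <= 1,
            n_chromosomes > 0, chrom_length_bp > 0, n_genes >= 0,
            n_variants_dense > 0, all(n_individuals > 0),
            fst >= 0, fst < 1, all(h2_target >= 0), all(h2_target <= 1),
            n_qtl > 0, ld_block_bp >= 0, n_founder_haplotypes >= 2,
            sex_ratio >= 0, sex_ratio <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(n_individuals)))
    names(n_individuals) <- paste0("pop", seq_along(n_individuals))
  structure(as.list(environment()), class = "sim_config")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("T","C","A","G"), c("T","C","A","G"),
                    c("T","C","A","G")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(s, function(x) paste(rev(strsplit(x, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

# one gene's local 5'->3' layout: exon/CDS/UTR segment table plus the CDS
# nucleotide sequence (ATG ... sense codons ... stop)
random_gene_layout <- function() {
  n_introns <- sample(1:3, 1)
  u5 <- sample(100:300, 1)
  u3 <- sample(100:500, 1)
  n_codons <- sample(60:220, 1)              # incl. start and stop
  cds_seq <- paste0("ATG",
                    paste(sample(SENSE_CODONS, n_codons - 2, replace = TRUE),
                          collapse = ""),
                    sample(STOP_CODONS, 1))
  cds_len <- 3L * n_codons
  cuts <- sort(sample(seq_len(cds_len - 1), n_introns))
  cds_parts <- diff(c(0L, cuts, cds_len))
  intron_len <- sample(1000:6000, n_introns, replace = TRUE)
  list(u5 = u5, u3 = u3, cds_parts = cds_parts, intron_len = intron_len,
       cds_seq = cds_seq)
}

#' Simulate a reference genome with gene models
#'
#' Random nucleotide chromosomes with non-overlapping genes on both
#' strands. Each gene has a 5' UTR, at least one intron, a CDS whose
#' length is a multiple of 3 and whose translation starts with Met and
#' contains no internal stop codon (the CDS nucleotides are written into
#' the reference, reverse-complemented on the minus strand), and a 3'
#' UTR. At least 40% of the genome is left intergenic.
#'
#' @param config a [sim_config()].
#' @return List with `reference` (named character vector of chromosome
#'   sequences) and `genes` (feature data.frame: `gene_id`, `chrom`,
#'   `strand`, `type`, `start`, `end`, `phase`; 1-based inclusive
#'   coordinates).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  L <- config$chrom_length_bp
  seqs <- lapply(chroms, function(ch)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  names(seqs) <- chroms
  feats <- list()
  if (config$n_genes > 0) {
    layouts <- replicate(config$n_genes, random_gene_layout(),
                         simplify = FALSE)
    glens <- vapply(layouts, function(x)
      x$u5 + x$u3 + sum(x$cds_parts) + sum(x$intron_len), numeric(1))
    if (sum(glens) > 0.6 * config$n_chromosomes * L)
      stop("gene placement impossible: requested genes cover ",
           sprintf("%.0f%%", 100 * sum(glens) / (config$n_chromosomes * L)),
           " of the genome; at most 60% may be genic ",
           "(>= 40% must remain intergenic)")
    chrom_of <- sort(sample(seq_len(config$n_chromosomes),
                            config$n_genes, replace = TRUE))
    for (ci in seq_len(config$n_chromosomes)) {
      idx <- which(chrom_of == ci)
      if (!length(idx)) next
      lens <- glens[idx]
      gap <- 1000L
      free <- L - sum(lens) - gap * (length(idx) + 1)
      if (free < 0)
        stop("gene placement impossible: chromosome ", chroms[ci],
             " cannot hold ", length(idx), " genes at this density")
      # random non-overlapping placement: distribute free space as gaps
      extra <- diff(c(0, sort(sample(seq_len(free + 1), length(idx)) - 1),
                      free))[seq_along(idx)]
      start <- gap + cumsum(c(0, head(lens, -1) + gap)) + cumsum(extra) + 1
      cds_pos <- cds_nt <- list()
      for (k in seq_along(idx)) {
        lay <- layouts[[idx[k]]]
        strand <- sample(c("+", "-"), 1)
        gf <- place_gene(lay, chroms[ci], start[k], strand,
                         paste0("gene", idx[k]))
        wr <- cds_write(gf, lay, strand)
        cds_pos[[k]] <- wr$pos; cds_nt[[k]] <- wr$nt
        feats[[length(feats) + 1]] <- gf
      }
      seqs[[ci]][unlist(cds_pos)] <- unlist(cds_nt)
    }
  }
  genes <- if (length(feats)) do.call(rbind, feats) else
    data.frame(gene_id = character(), chrom = character(),
               strand = character(), type = character(),
               start = integer(), end = integer(), phase = integer(),
               stringsAsFactors = FALSE)
  reference <- vapply(seqs, paste, character(1), collapse = "")
  names(reference) <- chroms
  list(reference = reference, genes = genes)
}

# lay out one gene's features in genome coordinates. Local 5'->3' order is
# [5'UTR][CDS1][intron]...[CDSk][3'UTR]; exon boundaries merge UTRs with
# their flanking CDS parts. On the minus strand the local layout is
# mirrored so the 5' UTR sits at the genome-coordinate right end.
place_gene <- function(lay, chrom, gstart, strand, gene_id) {
  seg_len <- c(lay$u5, lay$cds_parts[1])
  seg_type <- c("five_prime_UTR", "CDS")
  for (i in seq_along(lay$intron_len)) {
    seg_len <- c(seg_len, lay$intron_len[i], lay$cds_parts[i + 1])
    seg_type <- c(seg_type, "intron", "CDS")
  }
  seg_len <- c(seg_len, lay$u3)
  seg_type <- c(seg_type, "three_prime_UTR")
  if (strand == "-") { seg_len <- rev(seg_len); seg_type <- rev(seg_type) }
  ends <- cumsum(seg_len)
  starts <- gstart + c(0, head(ends, -1))
  ends <- gstart + ends - 1
  df <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                   type = seg_type, start = starts, end = ends,
                   phase = NA_integer_, stringsAsFactors = FALSE)
  # CDS phase: number of bases to skip to reach the next codon start,
  # accumulated in translation (5'->3') order
  cds <- df[df$type == "CDS", ]
  cds <- cds[order(if (strand == "+") cds$start else -cds$start), ]
  clen <- cds$end - cds$start + 1
  phase <- (3 - cumsum(c(0, head(clen, -1))) %% 3) %% 3
  df$phase[match(rownames(cds), rownames(df))] <- phase
  # exons: everything except introns, merged where adjacent
  nonint <- df[df$type != "intron", ]
  nonint <- nonint[order(nonint$start), ]
  ex_start <- ex_end <- integer(0)
  for (i in seq_len(nrow(nonint))) {
    if (length(ex_end) && nonint$start[i] == ex_end[length(ex_end)] + 1) {
      ex_end[length(ex_end)] <- nonint$end[i]
    } else {
      ex_start <- c(ex_start, nonint$start[i])
      ex_end <- c(ex_end, nonint$end[i])
    }
  }
  exons <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      type = "exon", start = ex_start, end = ex_end,
                      phase = NA_integer_, stringsAsFactors = FALSE)
  gene <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                     type = "gene", start = gstart,
                     end = max(df$end), phase = NA_integer_,
                     stringsAsFactors = FALSE)
  rbind(gene, exons, df[df$type != "intron", ])
}

# genomic positions and bases of one gene's CDS nucleotides
cds_write <- function(gf, lay, strand) {
  cds <- gf[gf$type == "CDS", ]
  cds <- cds[order(cds$start), ]
  nt <- strsplit(lay$cds_seq, "")[[1]]
  if (strand == "-") nt <- rev(chartr("ACGT", "TGCA", nt))
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i)
    seq.int(cds$start[i], cds$end[i])))
  list(pos = pos, nt = nt)
}

#' Simulate two-population genotypes with LD
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); per-population
#' frequencies follow the Balding-Nichols model with divergence `fst`.
#' Each population carries a pool of founder haplotypes drawn at its
#' frequencies; individual haplotypes are block-wise mosaics of founders
#' with switch probability `1 - exp(-gap / ld_block_bp)` between adjacent
#' variants, so r2 decays with distance. Genotypes are sums of two
#' independent haplotypes (Hardy-Weinberg within population). The chip
#' panel is an evenly spaced subsample of dense variant positions.
#'
#' @param config a [sim_config()].
#' @param reference optional reference from [simulate_genome()]; if
#'   supplied, ref alleles match the reference base at each position.
#' @return List with `dense` and `chip` [genotype_matrix()] objects
#'   (chip variants are a subset of dense variants).
#' @export
simulate_genotypes <- function(config, reference = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$fst >= 1) stop("fst must be < 1")
  set.seed(config$seed + 1L)
  nchr <- config$n_chromosomes
  L <- config$chrom_length_bp
  m <- config$n_variants_dense
  per_chr <- diff(round(seq(0, m, length.out = nchr + 1)))
  pos <- integer(0); chrom <- character(0)
  for (ci in seq_len(nchr)) {
    p <- sort(sample(seq_len(L), per_chr[ci]))
    pos <- c(pos, p)
    chrom <- c(chrom, rep(paste0("chr", ci), per_chr[ci]))
  }
  bases <- c("A", "C", "G", "T")
  if (!is.null(reference)) {
    refs <- ref_strings(reference)
    ref <- unlist(lapply(seq_len(nchr), function(ci) {
      idx <- chrom == paste0("chr", ci)
      substring(refs[[paste0("chr", ci)]], pos[idx], pos[idx])
    }))
  } else {
    ref <- sample(bases, m, replace = TRUE)
  }
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  p0 <- runif(m, 0.05, 0.95)
  pops <- names(config$n_individuals)
  H <- config$n_founder_haplotypes
  gap <- c(Inf, diff(pos))
  gap[c(1, which(diff(match(chrom, unique(chrom))) != 0) + 1)] <- Inf
  p_switch <- if (config$ld_block_bp > 0) 1 - exp(-gap / config$ld_block_bp)
              else rep(1, m)
  p_switch[!is.finite(gap)] <- 1
  geno <- NULL; samp <- NULL
  for (k in seq_along(pops)) {
    n <- config$n_individuals[[k]]
    pk <- if (config$fst > 0) {
      a <- p0 * (1 - config$fst) / config$fst
      b <- (1 - p0) * (1 - config$fst) / config$fst
      rbeta(m, a, b)
    } else p0
    founders <- matrix(rbinom(H * m, 1, rep(pk, each = H)), H, m)
    hap <- matrix(0L, 2L * n, m)
    for (i in seq_len(2L * n)) {
      sw <- runif(m) < p_switch
      sw[1] <- TRUE
      block <- cumsum(sw)
      fid <- sample.int(H, max(block), replace = TRUE)[block]
      hap[i, ] <- founders[fid + (seq_len(m) - 1L) * H]
    }
    gk <- hap[seq(1, 2 * n, 2), , drop = FALSE] +
          hap[seq(2, 2 * n, 2), , drop = FALSE]
    geno <- rbind(geno, gk)
    samp <- rbind(samp, data.frame(
      id = sprintf("%s_%04d", pops[k], seq_len(n)),
      population = pops[k],
      sex = ifelse(runif(n) < config$sex_ratio, "sire", "dam"),
      stringsAsFactors = FALSE))
  }
  if (config$missing_rate > 0) {
    nmiss <- rbinom(1, length(geno), config$missing_rate)
    geno[sample.int(length(geno), nmiss)] <- NA_integer_
  }
  variants <- data.frame(
    id = sprintf("%s_%d_%s_%s", chrom, pos, ref, alt),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    stringsAsFactors = FALSE)
  rownames(geno) <- samp$id
  dense <- genotype_matrix(geno, variants, samp)
  chip_idx <- unique(round(seq(1, m, length.out = config$n_variants_chip)))
  chip <- subset_genotypes(dense, variants = chip_idx)
  list(dense = dense, chip = chip)
}

#' Simulate growth-trait phenotypes with known genetic architecture
#'
#' For each trait, `n_qtl` causal variants are sampled (optionally with a
#' fraction forced into a named genomic class), additive effects are drawn
#' Normal(0, 1/n_qtl), true breeding values are the centered-dosage sums,
#' and the residual variance is chosen so the realized narrow-sense
#' heritability matches `h2_target`. Sex and population enter as fixed
#' effects. Raw "measured" columns (weight, age, backfat, loin depth) are
#' also emitted for the endpoint-adjustment functions.
#'
#' @param genotypes a [genotype_matrix()] (dense panel).
#' @param config a [sim_config()].
#' @param class_assignments optional result of [classify_variants()],
#'   required when `config$qtl_class != "uniform"`.
#' @return List with `phenotypes` (data.frame: id, population, sex,
#'   measured columns, one column per trait) and `truth` (list with per-
#'   trait QTL table, true-breeding-value matrix `tbv`, realized h2).
#'   When `h2_target` is 0 the `tbv` column holds the latent genetic
#'   values, which receive zero weight in the phenotype.
#' @export
simulate_phenotypes <- function(genotypes, config, class_assignments = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"),
            inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  g <- genotypes$geno
  n <- nrow(g); m <- ncol(g)
  traits <- config$trait_set
  h2 <- config$h2_target
  if (length(h2) == 1) h2 <- setNames(rep(h2, length(traits)), traits)
  stopifnot(all(traits %in% names(h2)))
  if (config$qtl_class != "uniform") {
    if (is.null(class_assignments))
      stop("class_assignments required when qtl_class != 'uniform'")
    in_class <- vapply(class_assignments$labels[genotypes$variants$id],
                       function(ll) config$qtl_class %in% ll, logical(1))
    n_forced <- round(config$n_qtl * config$qtl_class_fraction)
    if (sum(in_class) < n_forced)
      stop("class '", config$qtl_class, "' has only ", sum(in_class),
           " variants; cannot place ", n_forced, " QTL in it")
  }
  gimp <- g
  if (anyNA(gimp)) {      # mean-impute for truth computation only
    mu <- colMeans(gimp, na.rm = TRUE)
    idx <- which(is.na(gimp), arr.ind = TRUE)
    gimp[idx] <- mu[idx[, 2]]
  }
  sex <- genotypes$samples$sex
  popf <- factor(genotypes$samples$population)
  sex_eff <- ifelse(sex == "sire", 0.25, -0.25)
  pop_eff <- (as.integer(popf) - mean(as.integer(popf))) * 0.5
  tbv <- matrix(0, n, length(traits), dimnames = list(rownames(g), traits))
  qtl_tabs <- list()
  realized_h2 <- setNames(numeric(length(traits)), traits)
  phen <- data.frame(id = genotypes$samples$id,
                     population = genotypes$samples$population,
                     sex = sex, stringsAsFactors = FALSE)
  for (t in traits) {
    if (config$qtl_class != "uniform") {
      n_forced <- round(config$n_qtl * config$qtl_class_fraction)
      qtl <- c(sample(which(in_class), n_forced),
               sample(which(!in_class), config$n_qtl - n_forced))
    } else {
      qtl <- sample.int(m, config$n_qtl)
    }
    beta <- rnorm(config$n_qtl, 0, sqrt(1 / config$n_qtl))
    Zq <- scale(gimp[, qtl, drop = FALSE], center = TRUE, scale = FALSE)
    gv <- drop(Zq %*% beta)
    h2t <- h2[[t]]
    if (h2t == 0 || var(gv) == 0) {
      # latent genetic values kept in the truth table but given zero
      # weight in the phenotype: no genetic signal
      gv_used <- gv * 0
      e <- rnorm(n, 0, max(sd(gv), 1))
    } else {
      gv_used <- gv
      sde <- sqrt(var(gv) * (1 - h2t) / h2t)
      e <- rnorm(n, 0, sde)
    }
    y <- 10 + sex_eff + pop_eff + gv_used + e
    tbv[, t] <- gv
    realized_h2[t] <- var(gv_used) / (var(gv_used) + var(e))
    qtl_tabs[[t]] <- data.frame(trait = t,
                                id = genotypes$variants$id[qtl],
                                chrom = genotypes$variants$chrom[qtl],
                                pos = genotypes$variants$pos[qtl],
                                effect = beta, stringsAsFactors = FALSE)
    phen[[t]] <- y
  }
  phen$measured_weight_kg <- pmin(pmax(rnorm(n, 105, 8), 80), 130)
  phen$measured_age_d <- pmin(pmax(rnorm(n, 170, 12), 130), 220)
  phen$measured_bf_mm <- pmin(pmax(rnorm(n, 12, 2), 6), 25)
  phen$measured_lmd_mm <- pmin(pmax(rnorm(n, 55, 5), 35), 75)
  list(phenotypes = phen,
       truth = list(qtl = do.call(rbind, qtl_tabs), tbv = tbv,
                    realized_h2 = realized_h2))
}

#' Generate a complete synthetic dataset
#'
#' Runs [simulate_genome()], [simulate_genotypes()],
#' [classify_variants()] and [simulate_phenotypes()] in sequence.
#' Optionally writes FASTA, GFF3, dense and chip VCF, phenotype TSV and
#' truth TSV to a directory.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; created if missing.
#' @return List of class `sim_dataset` with elements `config`,
#'   `reference`, `genes`, `dense`, `chip`, `classes`, `phenotypes`,
#'   `truth` (and `paths` when `dir` is given).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  genome <- simulate_genome(config)
  gt <- simulate_genotypes(config, genome$reference)
  classes <- classify_variants(gt$dense$variants, genome$genes,
                               genome$reference)
  ph <- simulate_phenotypes(gt$dense, config, classes)
  out <- list(config = config, reference = genome$reference,
              genes = genome$genes, dense = gt$dense, chip = gt$chip,
              classes = classes, phenotypes = ph$phenotypes,
              truth = ph$truth)
  class(out) <- "sim_dataset"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      reference = file.path(dir, "reference.fa"),
      genes = file.path(dir, "genes.gff3"),
      genotypes_dense = file.path(dir, "genotypes_dense.vcf"),
      genotypes_chip = file.path(dir, "genotypes_chip.vcf"),
      phenotypes = file.path(dir, "phenotypes.tsv"),
      truth = file.path(dir, "truth_qtl.tsv"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(genome$reference), paths$reference)
    write_gff3(genome$genes, paths$genes)
    write_vcf(gt$dense, paths$genotypes_dense)
    write_vcf(gt$chip, paths$genotypes_chip)
    data.table::fwrite(ph$phenotypes, paths$phenotypes, sep = "\t")
    data.table::fwrite(ph$truth$qtl, paths$truth, sep = "\t")
    out$paths <- paths
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", nrow(x$dense$geno), "individuals;",
      ncol(x$dense$geno), "dense /", ncol(x$chip$geno), "chip variants;",
      nrow(x$genes[x$genes$type == "gene", ]), "genes;",
      length(x$config$trait_set), "traits\n")
  invisible(x)
}
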