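test_that("identical configs give bit-identical datasets", {
  cfg <- sim_config(seed = 5, n_individuals = c(a = 40, b = 30),
                    n_variants_dense = 300, n_variants_chip = 60,
                    n_genes = 8, n_chromosomes = 1,
                    chrom_length_bp = 500000L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$genes, d2$genes)
  expect_identical(d1$dense$geno, d2$dense$geno)
  expect_identical(d1$phenotypes, d2$phenotypes)
  # file outputs are byte-identical too
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  simulate_dataset(cfg, dir1); simulate_dataset(cfg, dir2)
  for (f in c("reference.fa", "genes.gff3", "genotypes_dense.vcf",
              "phenotypes.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})

test_that("simulated gene structures satisfy their invariants", {
  ds <- shared_ds()
  genes <- ds$genes
  for (gid in unique(genes$gene_id)) {
    sub <- genes[genes$gene_id == gid, ]
    cds <- sub[sub$type == "CDS", ]
    expect_gte(nrow(cds), 2)                       # >= 1 intron
    expect_equal(sum(cds$end - cds$start + 1) %% 3, 0)
    expect_equal(nrow(sub[sub$type == "five_prime_UTR", ]), 1)
    expect_equal(nrow(sub[sub$type == "three_prime_UTR", ]), 1)
    # exons sorted and non-overlapping
    ex <- sub[sub$type == "exon", ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] > ex$end[-nrow(ex)]))
  }
  # genes do not overlap each other
  gg <- genes[genes$type == "gene", ]
  for (ch in unique(gg$chrom)) {
    sub <- gg[gg$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    if (nrow(sub) > 1) expect_true(all(sub$start[-1] > sub$end[-nrow(sub)]))
  }
  # >= 40% of the genome stays intergenic
  genic <- sum(gg$end - gg$start + 1)
  expect_lt(genic, 0.6 * ds$config$n_chromosomes * ds$config$chrom_length_bp)
})

test_that("every emitted CDS translates without internal stop codons", {
  ds <- shared_ds()
  genes <- ds$genes
  ref <- Biostrings::DNAStringSet(ds$reference)
  for (gid in unique(genes$gene_id)) {
    cds <- genes[genes$gene_id == gid & genes$type == "CDS", ]
    cds <- cds[order(cds$start), ]
    s <- paste(vapply(seq_len(nrow(cds)), function(i)
      as.character(Biostrings::subseq(ref[[cds$chrom[1]]], cds$start[i],
                                      cds$end[i])), character(1)),
      collapse = "")
    if (cds$strand[1] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_equal(substr(aa, 1, 1), "M")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)),
                 label = paste("internal stop in", gid))
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("impossible gene densities fail with a clear message", {
  cfg <- sim_config(seed = 1, n_genes = 2000, n_chromosomes = 1,
                    chrom_length_bp = 100000L,
                    n_individuals = c(a = 10), n_variants_dense = 100,
                    n_variants_chip = 10)
  expect_error(simulate_genome(cfg), "gene placement impossible")
})

test_that("single-population genotypes without divergence sit in HWE", {
  cfg <- sim_config(seed = 6, n_individuals = c(one = 800), fst = 0,
                    n_variants_dense = 1200, n_variants_chip = 200,
                    n_genes = 0, missing_rate = 0, n_chromosomes = 1,
                    chrom_length_bp = 1000000L)
  gt <- simulate_genotypes(cfg)
  pv <- hwe_pvalues(gt$dense)
  polym <- minor_allele_freq(gt$dense) > 0
  expect_gte(mean(pv[polym] > 1e-6), 0.99)
})

test_that("LD decays with distance and vanishes when blocks are disabled", {
  r2_near_far <- function(ld_block, seed) {
    cfg <- sim_config(seed = seed, n_individuals = c(a = 150),
                      n_variants_dense = 600, n_variants_chip = 100,
                      n_genes = 0, ld_block_bp = ld_block,
                      missing_rate = 0, n_chromosomes = 1,
                      chrom_length_bp = 1000000L)
    gt <- simulate_genotypes(cfg)
    tab <- ld_decay(gt$dense, max_dist = 100000, bin_width = 10000)
    c(near = tab$mean_r2[1], far = tab$mean_r2[10])
  }
  with_ld <- sapply(1:5, function(s) r2_near_far(50000, s))
  expect_gt(mean(with_ld["near", ]), mean(with_ld["far", ]))
  no_ld <- sapply(1:3, function(s) r2_near_far(0, s + 10))
  expect_lt(abs(mean(no_ld["near", ]) - mean(no_ld["far", ])), 0.01)
})

test_that("population divergence separates IBS within vs between", {
  cfg <- sim_config(seed = 7, n_individuals = c(p1 = 80, p2 = 80),
                    fst = 0.15, n_variants_dense = 800,
                    n_variants_chip = 100, n_genes = 0,
                    missing_rate = 0, n_chromosomes = 1,
                    chrom_length_bp = 1000000L)
  gt <- simulate_genotypes(cfg)
  ibs <- ibs_matrix(gt$dense)
  pop <- gt$dense$samples$population
  within <- c(ibs[pop == "p1", pop == "p1"][upper.tri(diag(80))],
              ibs[pop == "p2", pop == "p2"][upper.tri(diag(80))])
  between <- ibs[pop == "p1", pop == "p2"]
  expect_gt(mean(within), mean(between))
})

test_that("chip variants are always a spaced subset of dense variants", {
  ds <- shared_ds()
  expect_true(all(ds$chip$variants$id %in% ds$dense$variants$id))
  expect_equal(ncol(ds$chip$geno), ds$config$n_variants_chip)
})

test_that("realized heritability tracks the target", {
  ds <- shared_ds()
  expect_true(all(abs(ds$truth$realized_h2 - ds$config$h2_target) < 0.02))
  # phenotype regressed on true breeding value has slope ~ 1
  y <- ds$phenotypes$ADG
  tbv <- ds$truth$tbv[, "ADG"]
  slope <- coef(lm(y ~ tbv + ds$phenotypes$sex +
                     ds$phenotypes$population))[2]
  expect_equal(unname(slope), 1, tolerance = 0.15)
})

test_that("heritability extremes behave as expected", {
  base <- function(h2, seed) {
    cfg <- sim_config(seed = seed, n_individuals = c(a = 400),
                      h2_target = h2, n_variants_dense = 500,
                      n_variants_chip = 100, n_genes = 0, n_qtl = 50,
                      missing_rate = 0, trait_set = "T1",
                      n_chromosomes = 1, chrom_length_bp = 1000000L)
    gt <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(gt$dense, cfg)
    yc <- precorrect_fixed_effects(ph$phenotypes$T1,
                                   data.frame(sex = ph$phenotypes$sex))
    cor(ph$truth$tbv[, "T1"], yc)
  }
  null_cors <- sapply(1:5, function(s) base(0, s))
  expect_lt(max(abs(null_cors)), 0.12)     # no genetic signal
  high <- base(0.99, 11)
  expect_gt(high, 0.95)                    # near-deterministic limit
})

test_that("class-enriched QTL placement respects the class and its limits", {
  ds <- shared_ds()
  cfg <- ds$config
  cfg$qtl_class <- "intron"
  cfg$qtl_class_fraction <- 1
  cfg$n_qtl <- 20L
  ph <- simulate_phenotypes(ds$dense, cfg, ds$classes)
  qtl_ids <- ph$truth$qtl$id[ph$truth$qtl$trait == "ADG"]
  in_class <- vapply(ds$classes$labels[qtl_ids],
                     function(ll) "intron" %in% ll, logical(1))
  expect_true(all(in_class))
  # asking for more QTL than the class holds fails loudly
  cfg$n_qtl <- 100000L
  expect_error(simulate_phenotypes(ds$dense, cfg, ds$classes),
               "cannot place")
  # enrichment without assignments is rejected
  cfg$n_qtl <- 10L
  expect_error(simulate_phenotypes(ds$dense, cfg, NULL),
               "class_assignments required")
})

test_that("written phenotype and truth tables carry the adjustment inputs", {
  ds <- shared_ds()
  ph <- ds$phenotypes
  expect_true(all(c("id", "population", "sex", "measured_weight_kg",
                    "measured_age_d", "measured_bf_mm", "measured_lmd_mm")
                  %in% names(ph)))
  expect_true(all(ds$config$trait_set %in% names(ph)))
  expect_true(all(ph$sex %in% c("sire", "dam")))
  # measured fields feed the adjustment functions without error
  adj <- adjust_growth_traits(ph)
  expect_true(all(is.finite(adj$lmp_adj)))
})
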