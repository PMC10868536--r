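# hand-built single-gene model on a 30 kb chromosome:
# plus-strand gene spanning 12001..13800 with
#   5'UTR 12001..12200, CDS 12201..12500 + 13301..13600 (intron between),
#   3'UTR 13601..13800
toy_gene_model <- function(strand = "+") {
  if (strand == "+") {
    feats <- data.frame(
      type  = c("gene", "exon", "exon", "five_prime_UTR", "CDS", "CDS",
                "three_prime_UTR"),
      start = c(12001, 12001, 13301, 12001, 12201, 13301, 13601),
      end   = c(13800, 12500, 13800, 12200, 12500, 13600, 13800))
  } else {
    # mirrored roles: 5'UTR at the right end of the span
    feats <- data.frame(
      type  = c("gene", "exon", "exon", "three_prime_UTR", "CDS", "CDS",
                "five_prime_UTR"),
      start = c(12001, 12001, 13301, 12001, 12201, 13301, 13601),
      end   = c(13800, 12500, 13800, 12200, 12500, 13600, 13800))
  }
  data.frame(gene_id = "g1", chrom = "chr1", strand = strand,
             type = feats$type, start = as.integer(feats$start),
             end = as.integer(feats$end), phase = NA_integer_,
             stringsAsFactors = FALSE)
}

toy_reference <- function() {
  set.seed(1)
  c(chr1 = paste(sample(c("A", "C", "T"), 30000, replace = TRUE),
                 collapse = ""))
}

toy_variants <- function(pos, ref, alt) {
  data.frame(id = paste0("v", seq_along(pos)), chrom = "chr1",
             pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

test_that("positional classes follow the 5 kb flank and gene-structure rules", {
  genes <- toy_gene_model("+")
  ref <- toy_reference()
  v <- toy_variants(c(9001, 12100, 12800, 13700, 16000, 20000, 1000),
                    ref = "A", alt = "G")
  # ref mismatch is tolerated for positional labels
  cls <- classify_variants(v, genes, ref)
  expect_equal(cls$labels[["v1"]], "upstream")        # 3 kb 5' of start
  expect_equal(cls$labels[["v2"]], "five_prime_utr")
  expect_equal(cls$labels[["v3"]], "intron")
  expect_equal(cls$labels[["v4"]], "three_prime_utr")
  expect_equal(cls$labels[["v5"]], "downstream")      # 2.2 kb past end
  expect_equal(cls$labels[["v6"]], "intergenic")      # > 5 kb from gene
  expect_equal(cls$labels[["v7"]], "intergenic")
})

test_that("mirroring a gene to the minus strand swaps the flank labels", {
  ref <- toy_reference()
  v <- toy_variants(c(9001, 16000), ref = "A", alt = "G")
  plus <- classify_variants(v, toy_gene_model("+"), ref)
  minus <- classify_variants(v, toy_gene_model("-"), ref)
  expect_equal(plus$labels[["v1"]], "upstream")
  expect_equal(minus$labels[["v1"]], "downstream")
  expect_equal(plus$labels[["v2"]], "downstream")
  expect_equal(minus$labels[["v2"]], "upstream")
})

test_that("coding SNVs split into synonymous and missense by codon translation", {
  genes <- toy_gene_model("+")
  # write a known ORF into the CDS: ATG GGA GGC ... ; CDS1 = 12201..12500
  s <- toy_reference()
  n_codons <- 200    # 600 bases over the two CDS segments
  orf <- paste0("ATG", paste(rep("GGA", n_codons - 2), collapse = ""), "TAA")
  cds_pos <- c(12201:12500, 13301:13600)
  sv <- strsplit(s, "")[[1]]
  sv[cds_pos] <- strsplit(orf, "")[[1]]
  s <- c(chr1 = paste(sv, collapse = ""))
  # codon 2 is GGA (Gly) at 12204..12206; third position A->G keeps Gly
  v <- toy_variants(c(12206, 12205), ref = c("A", "G"), alt = c("G", "T"))
  cls <- classify_variants(v, genes, s)
  expect_equal(cls$labels[["v1"]], "synonymous")      # GGA -> GGG
  expect_equal(cls$labels[["v2"]], "missense")        # GGA -> GTA (Val)
  # cross-check both calls with Biostrings translation
  for (i in 1:2) {
    codon_ref <- substr(s, 12204, 12206)
    codon_alt <- codon_ref
    substr(codon_alt, v$pos[i] - 12203, v$pos[i] - 12203) <- v$alt[i]
    same <- as.character(Biostrings::translate(Biostrings::DNAString(codon_ref))) ==
      as.character(Biostrings::translate(Biostrings::DNAString(codon_alt)))
    expect_equal(cls$labels[[v$id[i]]],
                 if (same) "synonymous" else "missense")
  }
  # an indel in the CDS gets a positional label only
  vin <- toy_variants(12210, ref = substr(s, 12210, 12211), alt = "A")
  vin$ref <- substr(s, 12210, 12211)
  expect_true("cds_indel" %in%
                classify_variants(vin, genes, s)$labels[["v1"]])
})

test_that("minus-strand coding calls translate on the reverse complement", {
  genes <- toy_gene_model("-")
  s <- toy_reference()
  # CDS in genome order: 12201..12500 + 13301..13600, translated right-to-left;
  # write the reverse-complemented ORF so translation starts at 13600
  n_codons <- 200
  orf <- paste0("ATG", paste(rep("GGA", n_codons - 2), collapse = ""), "TAA")
  orf_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(orf)))
  cds_pos <- c(12201:12500, 13301:13600)
  sv <- strsplit(s, "")[[1]]
  sv[cds_pos] <- strsplit(orf_rc, "")[[1]]
  s <- c(chr1 = paste(sv, collapse = ""))
  # genome position 13595: codon 2 (GGA), third base; genome base is T
  # (complement of A); T->C makes GGA -> GGG: synonymous
  v <- toy_variants(13595, ref = substr(s, 13595, 13595), alt = "C")
  cls <- classify_variants(v, genes, s)
  expect_equal(cls$labels[["v1"]], "synonymous")
})

test_that("class panels are reproducible, pure and size-controlled", {
  ds <- shared_ds()
  cls <- ds$classes
  sizes <- table(unlist(lapply(cls$labels, unique)))
  have <- names(sizes)[sizes >= 20]
  pick <- head(intersect(c("intron", "intergenic", "upstream", "downstream"),
                         have), 3)
  panels <- build_class_panels(cls, pick, target_size = "min", seed = 4)
  sz <- min(sizes[pick])
  for (p in panels) expect_length(p$ids, sz)
  # purity: every sampled id carries its class label
  for (cl in pick) {
    member <- vapply(cls$labels[panels[[cl]]$ids],
                     function(ll) cl %in% ll, logical(1))
    expect_true(all(member))
  }
  # determinism under seed; difference across seeds
  again <- build_class_panels(cls, pick, target_size = "min", seed = 4)
  expect_identical(panels[[1]]$ids, again[[1]]$ids)
  other <- build_class_panels(cls, pick, target_size = "min", seed = 5)
  expect_false(identical(panels[[1]]$ids, other[[1]]$ids))
  # explicit target larger than a class fails naming it
  expect_error(build_class_panels(cls, pick, target_size = 1e7),
               "smaller than target")
})

test_that("panel intersection keeps order and rejects empty overlap", {
  p <- panel_spec("toy", paste0("v", 1:10))
  expect_equal(intersect_panels(p, paste0("v", 1:10))$ids, p$ids)
  half <- intersect_panels(p, paste0("v", c(2, 4, 6, 8, 10)))
  expect_equal(half$ids, paste0("v", c(2, 4, 6, 8, 10)))
  expect_error(intersect_panels(p, paste0("w", 1:10)), "no variants in common")
})

test_that("deduplication against a base set removes exactly the shared ids", {
  p <- panel_spec("toy", paste0("v", 1:6))
  expect_equal(deduplicate_against_base(p, paste0("w", 1:3))$ids, p$ids)
  expect_length(deduplicate_against_base(p, paste0("v", 1:6))$ids, 0)
  mixed <- deduplicate_against_base(p, paste0("v", c(2, 5)))
  expect_equal(mixed$ids, paste0("v", c(1, 3, 4, 6)))
})

test_that("every simulated variant gets a label and intergenic is the default", {
  ds <- shared_ds()
  expect_true(all(lengths(ds$classes$labels) >= 1))
  # intergenic never co-occurs with another label
  for (ll in ds$classes$labels[1:500])
    if ("intergenic" %in% ll) expect_length(ll, 1)
  # no-gene genome: everything intergenic
  cfg0 <- sim_config(seed = 2, n_genes = 0,
                     n_individuals = c(a = 10), n_variants_dense = 50,
                     n_variants_chip = 10, n_chromosomes = 1,
                     chrom_length_bp = 100000L)
  gen0 <- simulate_genome(cfg0)
  expect_equal(nrow(gen0$genes), 0)
  v0 <- data.frame(id = "x", chrom = "chr1", pos = 500L, ref = "A",
                   alt = "G")
  expect_equal(classify_variants(v0, gen0$genes,
                                 gen0$reference)$labels[["x"]],
               "intergenic")
})
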