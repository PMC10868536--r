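GENETIC_CODE_TABLE <- Biostrings::GENETIC_CODE

FLANK_BP <- 5000L   # upstream/downstream window size

# reference sequences as a named character vector, whatever the input form
ref_strings <- function(reference) {
  if (is.character(reference)) return(reference)
  setNames(vapply(seq_along(reference),
                  function(i) as.character(reference[[i]]), character(1)),
           names(reference))
}

#' Classify variants into genomic classes
#'
#' Positional consequence classification against single-transcript gene
#' models: `intron`, `five_prime_utr`, `three_prime_utr`,
#' `noncoding_exon`, `upstream` (within 5 kb of the gene start,
#' strand-aware), `downstream` (within 5 kb of the gene end), and for
#' SNVs inside a CDS `synonymous` or `missense` by translating the
#' affected codon for the ref and alt allele. Variants with no other
#' label are `intergenic`. A variant overlapping several genes carries
#' the union of labels. INDELs inside a CDS are labelled `cds_indel`
#' (no synonymous/missense call). If a variant's ref allele disagrees
#' with the reference base, it is classified by position only and
#' counted in the `ref_mismatch` attribute.
#'
#' @param variants data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param genes gene-model feature data.frame as produced by
#'   [simulate_genome()] or [read_gff3()].
#' @param reference chromosome sequences named by chromosome: a
#'   character vector or a [Biostrings::DNAStringSet].
#' @return Object of class `class_assignment`: list with `labels` (named
#'   list, one character vector per variant id) and `table` (data.frame
#'   `id`, `labels` comma-joined).
#' @export
classify_variants <- function(variants, genes, reference) {
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  m <- nrow(variants)
  labels <- vector("list", m)
  names(labels) <- variants$id
  ref_chars <- ref_strings(reference)
  gene_rows <- genes[genes$type == "gene", , drop = FALSE]
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  add_label <- function(hits, lab) {
    qh <- S4Vectors::queryHits(hits)
    for (i in unique(qh)) labels[[i]] <<- c(labels[[i]], lab)
  }
  mk_gr <- function(df) GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(pmax(df$start, 1L), df$end))
  if (nrow(gene_rows)) {
    plus <- gene_rows$strand == "+"
    up <- data.frame(
      chrom = gene_rows$chrom,
      start = ifelse(plus, gene_rows$start - FLANK_BP, gene_rows$end + 1L),
      end   = ifelse(plus, gene_rows$start - 1L, gene_rows$end + FLANK_BP))
    down <- data.frame(
      chrom = gene_rows$chrom,
      start = ifelse(plus, gene_rows$end + 1L, gene_rows$start - FLANK_BP),
      end   = ifelse(plus, gene_rows$end + FLANK_BP, gene_rows$start - 1L))
    add_label(GenomicRanges::findOverlaps(vgr, mk_gr(up)), "upstream")
    add_label(GenomicRanges::findOverlaps(vgr, mk_gr(down)), "downstream")
    utr5 <- genes[genes$type == "five_prime_UTR", , drop = FALSE]
    utr3 <- genes[genes$type == "three_prime_UTR", , drop = FALSE]
    exon <- genes[genes$type == "exon", , drop = FALSE]
    cds  <- genes[genes$type == "CDS", , drop = FALSE]
    if (nrow(utr5))
      add_label(GenomicRanges::findOverlaps(vgr, mk_gr(utr5)),
                "five_prime_utr")
    if (nrow(utr3))
      add_label(GenomicRanges::findOverlaps(vgr, mk_gr(utr3)),
                "three_prime_utr")
    # intron: inside the gene span but in no exon of it
    in_gene <- GenomicRanges::findOverlaps(vgr, mk_gr(gene_rows))
    in_exon <- unique(S4Vectors::queryHits(
      GenomicRanges::findOverlaps(vgr, mk_gr(exon))))
    intron_idx <- setdiff(unique(S4Vectors::queryHits(in_gene)), in_exon)
    for (i in intron_idx) labels[[i]] <- c(labels[[i]], "intron")
    # noncoding exon: in exon, in no CDS/UTR
    coding_or_utr <- unique(c(
      if (nrow(cds)) S4Vectors::queryHits(
        GenomicRanges::findOverlaps(vgr, mk_gr(cds))),
      if (nrow(utr5)) S4Vectors::queryHits(
        GenomicRanges::findOverlaps(vgr, mk_gr(utr5))),
      if (nrow(utr3)) S4Vectors::queryHits(
        GenomicRanges::findOverlaps(vgr, mk_gr(utr3)))))
    for (i in setdiff(in_exon, coding_or_utr))
      labels[[i]] <- c(labels[[i]], "noncoding_exon")
    # coding consequences
    n_mismatch <- 0L
    if (nrow(cds)) {
      cds_map <- build_cds_maps(cds)
      hits <- GenomicRanges::findOverlaps(vgr, mk_gr(cds))
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      for (j in seq_along(qh)) {
        vi <- qh[j]
        gene_id <- cds$gene_id[sh[j]]
        is_snv <- nchar(variants$ref[vi]) == 1 && nchar(variants$alt[vi]) == 1
        if (!is_snv) {
          labels[[vi]] <- c(labels[[vi]], "cds_indel")
          next
        }
        ref_base <- substring(ref_chars[[variants$chrom[vi]]],
                              variants$pos[vi], variants$pos[vi])
        if (!identical(ref_base, variants$ref[vi])) {
          n_mismatch <- n_mismatch + 1L
          next
        }
        lab <- coding_consequence(variants$pos[vi], variants$alt[vi],
                                  cds_map[[gene_id]],
                                  ref_chars[[variants$chrom[vi]]])
        labels[[vi]] <- c(labels[[vi]], lab)
      }
    } else n_mismatch <- 0L
  } else n_mismatch <- 0L
  labels <- lapply(labels, function(ll)
    if (is.null(ll)) "intergenic" else unique(ll))
  tab <- data.frame(id = variants$id,
                    labels = vapply(labels, paste, character(1),
                                    collapse = ","),
                    stringsAsFactors = FALSE)
  structure(list(labels = labels, table = tab),
            class = "class_assignment",
            ref_mismatch = n_mismatch)
}

# per-gene map from genomic position to CDS-local (translation-order)
# index, plus strand
build_cds_maps <- function(cds) {
  out <- list()
  for (gid in unique(cds$gene_id)) {
    seg <- cds[cds$gene_id == gid, , drop = FALSE]
    strand <- seg$strand[1]
    seg <- seg[order(seg$start), , drop = FALSE]
    gpos <- unlist(lapply(seq_len(nrow(seg)), function(i)
      seq.int(seg$start[i], seg$end[i])))
    if (strand == "-") gpos <- rev(gpos)
    out[[gid]] <- list(gpos = gpos, strand = strand,
                       local = setNames(seq_along(gpos), gpos))
  }
  out
}

coding_consequence <- function(pos, alt, map, chrom_chars) {
  loc <- map$local[[as.character(pos)]]
  codon_i <- (loc - 1L) %/% 3L
  idx <- codon_i * 3L + 1:3            # local indices of the codon
  idx <- idx[idx <= length(map$gpos)]  # guard truncated tail
  gp <- map$gpos[idx]
  bases <- substring(chrom_chars, gp, gp)
  if (map$strand == "-") bases <- chartr("ACGT", "TGCA", bases)
  ref_codon <- paste(bases, collapse = "")
  alt_b <- if (map$strand == "-") chartr("ACGT", "TGCA", alt) else alt
  bases[match(loc, idx)] <- alt_b
  alt_codon <- paste(bases, collapse = "")
  if (nchar(ref_codon) < 3) return("cds_partial")
  aa_ref <- GENETIC_CODE_TABLE[[ref_codon]]
  aa_alt <- GENETIC_CODE_TABLE[[alt_codon]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "missense"
}

#' Build equal-size class panels
#'
#' For each requested class, draws a uniform random subsample (without
#' replacement) of exactly `target_size` variant ids carrying that class
#' label, so downstream model comparisons control for panel size.
#'
#' @param assignments a [classify_variants()] result.
#' @param classes character vector of class labels.
#' @param target_size integer, or `"min"` for the size of the smallest
#'   requested class.
#' @param seed RNG seed making panels reproducible.
#' @return Named list of `panel_spec` objects (`name`, `ids`,
#'   `provenance`).
#' @export
build_class_panels <- function(assignments, classes, target_size = "min",
                               seed = 1L) {
  stopifnot(inherits(assignments, "class_assignment"))
  members <- lapply(classes, function(cl)
    names(assignments$labels)[vapply(assignments$labels,
                                     function(ll) cl %in% ll, logical(1))])
  names(members) <- classes
  sizes <- lengths(members)
  if (identical(target_size, "min")) target_size <- min(sizes)
  target_size <- as.integer(target_size)
  small <- sizes < target_size
  if (any(small))
    stop("class(es) smaller than target size ", target_size, ": ",
         paste(sprintf("%s (%d)", classes[small], sizes[small]),
               collapse = ", "))
  set.seed(seed)
  panels <- lapply(classes, function(cl)
    panel_spec(cl, sort(sample(members[[cl]], target_size)),
               provenance = list(source = "class", class = cl, seed = seed)))
  names(panels) <- classes
  panels
}

#' Construct a variant panel
#'
#' @param name panel name.
#' @param ids ordered unique variant ids.
#' @param provenance free-form list recording how the panel was made
#'   (class or GWAS, source population, seed).
#' @return Object of class `panel_spec`.
#' @export
panel_spec <- function(name, ids, provenance = list()) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("panel ids must be unique")
  structure(list(name = name, ids = ids, provenance = provenance),
            class = "panel_spec")
}

#' @export
print.panel_spec <- function(x, ...) {
  cat(sprintf("panel '%s': %d variants\n", x$name, length(x$ids)))
  invisible(x)
}

as_variant_ids <- function(x) {
  if (inherits(x, "genotype_matrix")) return(x$variants$id)
  if (inherits(x, "panel_spec")) return(x$ids)
  if (is.data.frame(x)) return(x$id)
  as.character(x)
}

#' Intersect a panel with the variants available in a dataset
#'
#' Keeps, in panel order, the panel ids present among the available
#' variants; used to carry discovery-population panels over to a
#' validation population's marker set.
#'
#' @param panel a [panel_spec()].
#' @param available a `genotype_matrix`, variants data.frame, panel, or
#'   character vector of variant ids.
#' @return A `panel_spec` restricted to the available ids.
#' @export
intersect_panels <- function(panel, available) {
  stopifnot(inherits(panel, "panel_spec"))
  avail <- as_variant_ids(available)
  keep <- panel$ids[panel$ids %in% avail]
  if (!length(keep))
    stop("panel '", panel$name,
         "' has no variants in common with the available set")
  panel_spec(panel$name, keep,
             c(panel$provenance, list(intersected = TRUE)))
}

#' Remove panel variants already present in a base marker set
#'
#' Ensures no variant enters both genetic components of a two-component
#' model: the feature panel is purged of any id found in the base set.
#'
#' @param panel a [panel_spec()].
#' @param base_variants base marker set (same accepted types as in
#'   [intersect_panels()]).
#' @return A `panel_spec` (possibly empty).
#' @export
deduplicate_against_base <- function(panel, base_variants) {
  stopifnot(inherits(panel, "panel_spec"))
  base <- as_variant_ids(base_variants)
  panel_spec(panel$name, setdiff(panel$ids, base),
             c(panel$provenance, list(deduplicated = TRUE)))
}

#' Write gene models to a GFF3 file
#'
#' @param genes gene-model feature data.frame (`gene_id`, `chrom`,
#'   `strand`, `type`, `start`, `end`, `phase`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!nrow(genes)) return(invisible(path))
  attr_of <- function(row) {
    if (row$type == "gene") sprintf("ID=%s", row$gene_id)
    else sprintf("Parent=%s", row$gene_id)
  }
  for (gid in unique(genes$gene_id)) {
    sub <- genes[genes$gene_id == gid, , drop = FALSE]
    sub <- sub[order(sub$type != "gene", sub$start), , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      row <- sub[i, ]
      writeLines(paste(row$chrom, "featuregp", row$type, row$start, row$end,
                       ".", row$strand,
                       ifelse(is.na(row$phase), ".", row$phase),
                       attr_of(row), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Imports gene/exon/CDS/UTR features (via rtracklayer) into the internal
#' gene-model data.frame used by [classify_variants()].
#'
#' @param path GFF3 file path.
#' @return Gene-model feature data.frame.
#' @export
read_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff3 requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  keep <- df$type %in% c("gene", "exon", "CDS", "five_prime_UTR",
                         "three_prime_UTR")
  df <- df[keep, , drop = FALSE]
  gene_id <- ifelse(df$type == "gene", df$ID,
                    vapply(df$Parent, function(p)
                      if (length(p)) p[[1]] else NA_character_, character(1)))
  out <- data.frame(gene_id = gene_id, chrom = as.character(df$seqnames),
                    strand = as.character(df$strand),
                    type = as.character(df$type),
                    start = df$start, end = df$end,
                    phase = if ("phase" %in% names(df))
                      as.integer(as.character(df$phase)) else NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
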