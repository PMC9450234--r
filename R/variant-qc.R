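#' Genotype-level quality filtering
#'
#' Masks individual genotype calls whose read depth or genotype quality falls
#' below threshold, and drops sites whose variant QUAL is below threshold.
#' Thresholds follow common resequencing practice for low-coverage diploid
#' calls: depth < 3 or GQ < 5 masks the call, QUAL < 20 removes the site.
#'
#' @param gm a [geno_matrix()] with DP, GQ and QUAL annotations.
#' @param min_depth minimum per-genotype read depth.
#' @param min_gq minimum per-genotype quality.
#' @param min_qual minimum site QUAL.
#' @return Filtered `geno_matrix` (failing genotypes set to NA, low-QUAL
#'   sites removed).
#' @export
filter_genotypes <- function(gm, min_depth = 3, min_gq = 5, min_qual = 20) {
  if (is.null(gm$dp)) stop("per-genotype DP field is required but absent")
  if (is.null(gm$gq)) stop("per-genotype GQ field is required but absent")
  if (is.null(gm$qual)) stop("per-site QUAL field is required but absent")
  mask <- gm$dp < min_depth | gm$gq < min_gq
  gm$geno[mask] <- NA_integer_
  keep <- !is.na(gm$qual) & gm$qual >= min_qual
  out <- gm_subset(gm, sites = keep)
  out$chrom_len <- gm$chrom_len
  out
}

#' Population-level site filtering
#'
#' Removes sites with minor allele frequency below `min_maf` (computed from
#' non-missing alleles only) or genotype missingness above `max_missing`.
#' The defaults (MAF < 0.05 removed, missing ratio > 0.2 removed) suit
#' population-genetic scans; association scans typically relax them
#' (e.g. MAF >= 0.01, missingness <= 0.5).
#'
#' @param gm a [geno_matrix()].
#' @param min_maf sites with MAF strictly below this are removed (in
#'   [0, 0.5]); a site at exactly `min_maf` is retained.
#' @param max_missing sites with missing fraction strictly above this are
#'   removed (in [0, 1]).
#' @return Filtered `geno_matrix`.
#' @export
filter_population <- function(gm, min_maf = 0.05, max_missing = 0.2) {
  if (min_maf < 0 || min_maf > 0.5) stop("min_maf must lie in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) stop("max_missing must lie in [0, 1]")
  if (!length(gm$pos)) stop("no sites to filter")
  st <- site_allele_stats(gm, seq_along(gm$samples))
  maf <- pmin(st$p, 1 - st$p)
  miss <- 1 - st$n_dip / length(gm$samples)
  keep <- !is.na(maf) & maf >= min_maf & miss <= max_missing
  out <- gm_subset(gm, sites = keep)
  out$chrom_len <- gm$chrom_len
  out
}

#' Positional variant annotation against a gene model
#'
#' Classifies each variant into exactly one positional category with
#' precedence exonic > splicing > intronic > upstream1kb > downstream1kb >
#' intergenic. With gene-only models every in-gene position is exonic; when
#' exon features are present, in-gene positions outside exons are intronic
#' and positions within 2 bp of an intron boundary are splicing. Upstream and
#' downstream are the 1-kb flanks, oriented by strand. Coding-effect calls
#' require CDS features with frame and are reported NA otherwise.
#'
#' @param gm a [geno_matrix()].
#' @param gene_model data.frame from [read_gene_models()] or
#'   [simulate_gene_models()] (1-based inclusive coordinates, sorted).
#' @param flank_bp size of the up/downstream flanks.
#' @param splice_bp distance from an intron boundary called splicing.
#' @return data.frame with chrom, pos, category, coding_effect.
#' @export
annotate_variants <- function(gm, gene_model, flank_bp = 1000,
                              splice_bp = 2) {
  genes <- gene_model[if ("type" %in% names(gene_model))
    gene_model$type == "gene" else TRUE, , drop = FALSE]
  if (!nrow(genes)) stop("gene model contains no gene features")
  if (any(genes$end < genes$start)) stop("malformed gene model: end < start")
  for (ch in unique(genes$chrom)) {
    s <- genes$start[genes$chrom == ch]
    if (is.unsorted(s)) stop("gene model must be sorted by position")
  }
  exons <- gene_model[if ("type" %in% names(gene_model))
    gene_model$type == "exon" else FALSE, , drop = FALSE]
  n <- length(gm$pos)
  category <- rep("intergenic", n)
  strand <- if ("strand" %in% names(genes)) genes$strand else rep("+", nrow(genes))

  ir_sites <- split(seq_len(n), gm$chrom)
  for (ch in names(ir_sites)) {
    idx <- ir_sites[[ch]]
    pos <- gm$pos[idx]
    q <- IRanges::IRanges(start = pos, width = 1)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) next
    gs <- strand[genes$chrom == ch]
    gene_ir <- IRanges::IRanges(g$start, g$end)
    # flanks, orientation by strand
    up_start <- ifelse(gs == "-", g$end + 1L, pmax(1L, g$start - flank_bp))
    up_end <- ifelse(gs == "-", g$end + flank_bp, g$start - 1L)
    dn_start <- ifelse(gs == "-", pmax(1L, g$start - flank_bp), g$end + 1L)
    dn_end <- ifelse(gs == "-", g$start - 1L, g$end + flank_bp)
    ok_up <- up_end >= up_start
    ok_dn <- dn_end >= dn_start
    hit_dn <- IRanges::overlapsAny(
      q, IRanges::IRanges(dn_start[ok_dn], dn_end[ok_dn]))
    category[idx][hit_dn] <- "downstream1kb"
    hit_up <- IRanges::overlapsAny(
      q, IRanges::IRanges(up_start[ok_up], up_end[ok_up]))
    category[idx][hit_up] <- "upstream1kb"
    in_gene <- IRanges::overlapsAny(q, gene_ir)
    ex <- exons[exons$chrom == ch, , drop = FALSE]
    if (nrow(ex)) {
      ex_ir <- IRanges::IRanges(ex$start, ex$end)
      in_exon <- IRanges::overlapsAny(q, ex_ir)
      category[idx][in_gene & !in_exon] <- "intronic"
      # splicing: within splice_bp of an intron boundary, i.e. near an exon
      # edge that faces an intron (interior exon edges)
      intr <- intron_ranges(g, ex)
      if (length(intr)) {
        near <- IRanges::overlapsAny(
          q, IRanges::IRanges(IRanges::start(intr) - splice_bp + 1L,
                              IRanges::start(intr) + splice_bp - 1L))
        near <- near | IRanges::overlapsAny(
          q, IRanges::IRanges(IRanges::end(intr) - splice_bp + 1L,
                              IRanges::end(intr) + splice_bp - 1L))
        category[idx][in_gene & !in_exon & near] <- "splicing"
      }
      category[idx][in_exon] <- "exonic"
    } else {
      category[idx][in_gene] <- "exonic"
    }
  }
  has_cds <- "type" %in% names(gene_model) &&
    any(gene_model$type == "CDS") && "frame" %in% names(gene_model)
  coding_effect <- rep(NA_character_, n)
  if (has_cds) {
    coding_effect[category == "exonic"] <-
      classify_coding_effect(gm, gene_model)
  }
  data.frame(chrom = gm$chrom, pos = gm$pos, category = category,
             coding_effect = coding_effect, stringsAsFactors = FALSE)
}

# introns of genes with exon annotation: gene span minus exons, per gene
intron_ranges <- function(genes, exons) {
  out <- IRanges::IRanges()
  for (i in seq_len(nrow(genes))) {
    ex <- exons[exons$gene_id == genes$gene_id[i], , drop = FALSE]
    if (nrow(ex) < 2) next
    span <- IRanges::IRanges(genes$start[i], genes$end[i])
    intr <- IRanges::setdiff(span, IRanges::IRanges(ex$start, ex$end))
    out <- c(out, intr)
  }
  out
}

# frame/stop-level coding effects for SNVs and indels inside CDS; indel
# length not a multiple of 3 -> frameshift, else non-frameshift. SNVs are
# split synonymous/nonsynonymous only when codon context is reconstructable;
# this simplified classifier reports length-based classes and NA otherwise.
classify_coding_effect <- function(gm, gene_model) {
  exonic <- rep(NA_character_, length(gm$pos))
  len_diff <- abs(nchar(gm$ref) - nchar(gm$alt))
  is_indel <- len_diff > 0
  exonic[is_indel & len_diff %% 3 != 0] <- "frameshift"
  exonic[is_indel & len_diff %% 3 == 0] <- "non-frameshift"
  exonic[!is_indel]
}

#' Summarize a variant set
#'
#' Counts SNPs and indels (alleles differing in length, <= 5 bp by
#' convention), totals, per-category counts when an annotation table is
#' supplied, and the percentage of SNPs in coding (exonic) regions rounded
#' to two decimals.
#'
#' @param gm a [geno_matrix()], or NULL when supplying counts directly.
#' @param ann optional annotation table from [annotate_variants()].
#' @param n_snps,n_indels,coding_snps direct counts, used when `gm` is NULL
#'   (e.g. to aggregate externally computed tallies).
#' @return list with n_snps, n_indels, n_total, coding_snps, coding_pct and
#'   category_counts.
#' @export
summarize_variants <- function(gm = NULL, ann = NULL, n_snps = NULL,
                               n_indels = NULL, coding_snps = NULL) {
  category_counts <- NULL
  if (!is.null(gm)) {
    is_indel <- nchar(gm$ref) != nchar(gm$alt)
    n_snps <- sum(!is_indel)
    n_indels <- sum(is_indel)
    if (!is.null(ann)) {
      category_counts <- table(ann$category)
      coding_snps <- sum(ann$category == "exonic" & !is_indel)
    }
  }
  if (is.null(n_snps)) n_snps <- 0
  if (is.null(n_indels)) n_indels <- 0
  n_total <- n_snps + n_indels
  coding_pct <- if (!is.null(coding_snps) && n_snps > 0)
    round(100 * coding_snps / n_snps, 2) else NA_real_
  list(n_snps = n_snps, n_indels = n_indels, n_total = n_total,
       coding_snps = coding_snps, coding_pct = coding_pct,
       category_counts = category_counts)
}
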