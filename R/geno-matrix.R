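#' Construct a genotype matrix
#'
#' The central container for diploid genotype data: a sites-by-accessions
#' integer matrix of derived (ALT) allele counts, with per-site coordinates
#' and per-accession population labels. Genotypes are coded 0 (homozygous
#' reference), 1 (heterozygous), 2 (homozygous derived) and `NA` (missing).
#' Positions are 1-based, as in VCF; all interval operations elsewhere in the
#' package use 0-based half-open coordinates and convert on the way in.
#'
#' @param geno integer matrix, sites x accessions, values in \{0,1,2,NA\}.
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions, strictly increasing within
#'   each chromosome.
#' @param ref,alt single-character reference / alternate alleles per site.
#'   The reference allele is taken as ancestral throughout.
#' @param samples accession identifiers (column names).
#' @param pops population label per accession (character or factor).
#' @param qual optional per-site variant QUAL score.
#' @param dp,gq optional per-genotype depth and genotype-quality matrices of
#'   the same dimension as `geno`.
#'
#' @return An object of class `geno_matrix`: a list with the validated
#'   components above.
#' @export
geno_matrix <- function(geno, chrom, pos, ref = NULL, alt = NULL,
                        samples = NULL, pops = NULL,
                        qual = NULL, dp = NULL, gq = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  n_sites <- nrow(geno)
  n_samp <- ncol(geno)
  if (is.null(samples)) samples <- colnames(geno)
  if (is.null(samples))
    samples <- sprintf("S%d", seq_len(n_samp))
  if (is.null(pops)) pops <- rep("pop1", n_samp)
  pops <- as.character(pops)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  stopifnot(length(chrom) == n_sites, length(pos) == n_sites,
            length(samples) == n_samp, length(pops) == n_samp)
  bad <- geno[!is.na(geno)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  # sorted within chromosome; ties allowed so multiallelic records split
  # into biallelic ones can share a position
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (is.unsorted(p))
      stop("positions must be sorted within chromosome ", ch)
  }
  if (is.null(ref)) ref <- rep("A", n_sites)
  if (is.null(alt)) alt <- rep("T", n_sites)
  if (!is.null(qual)) stopifnot(length(qual) == n_sites)
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(geno)))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(geno)))
  colnames(geno) <- samples
  structure(list(geno = geno, chrom = chrom, pos = pos,
                 ref = as.character(ref), alt = as.character(alt),
                 samples = as.character(samples), pops = pops,
                 qual = qual, dp = dp, gq = gq),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$geno), "sites x", ncol(x$geno), "accessions\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  tab <- table(x$pops)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$geno))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param sites logical or integer index over sites.
#' @param samples logical or integer index over accessions, or a character
#'   vector of accession ids or population labels.
#' @return A `geno_matrix` restricted to the selected sites/accessions.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_along(gm$pos)
  if (is.null(samples)) samples <- seq_along(gm$samples)
  if (is.character(samples)) {
    idx <- which(gm$samples %in% samples | gm$pops %in% samples)
    if (!length(idx)) stop("no accessions match the requested labels")
    samples <- idx
  }
  geno_matrix(gm$geno[sites, samples, drop = FALSE],
              gm$chrom[sites], gm$pos[sites],
              gm$ref[sites], gm$alt[sites],
              gm$samples[samples], gm$pops[samples],
              qual = gm$qual[sites],
              dp = if (!is.null(gm$dp)) gm$dp[sites, samples, drop = FALSE],
              gq = if (!is.null(gm$gq)) gm$gq[sites, samples, drop = FALSE])
}

# Per-site derived-allele frequency and called-allele count for a set of
# accessions (columns). Missing genotypes are excluded from both counts.
site_allele_stats <- function(gm, cols) {
  g <- gm$geno[, cols, drop = FALSE]
  called <- !is.na(g)
  an <- 2L * rowSums(called)
  ac <- rowSums(g, na.rm = TRUE)
  het <- rowSums(g == 1L, na.rm = TRUE)
  list(p = ifelse(an > 0, ac / an, NA_real_), an = an, ac = ac,
       n_dip = rowSums(called), n_het = het)
}

pop_cols <- function(gm, pop) {
  cols <- which(gm$pops %in% pop)
  if (!length(cols)) stop("population not found: ", paste(pop, collapse = ","))
  cols
}
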