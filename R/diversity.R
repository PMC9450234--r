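#' Build a sliding-window grid
#'
#' Windows are 0-based half-open. The default grid (500-kb windows sliding
#' in 125-kb steps) matches standard whole-genome scan practice for large
#' plant genomes; the final window is truncated at the chromosome end.
#'
#' @param chrom_len named vector of chromosome lengths in bp.
#' @param window window size in bp.
#' @param step step size in bp (<= window); `step = window` gives a
#'   non-overlapping partition.
#' @return data.frame (chrom, start, end), sorted.
#' @export
make_windows <- function(chrom_len, window = 5e5, step = 1.25e5) {
  if (window <= 0) stop("window must be positive")
  if (step > window) stop("step must not exceed window")
  out <- lapply(names(chrom_len), function(ch) {
    len <- chrom_len[[ch]]
    start <- seq(0, max(0, len - 1), by = step)
    start <- start[start < len]
    data.frame(chrom = ch, start = start, end = pmin(start + window, len))
  })
  do.call(rbind, out)
}

# per-site unbiased heterozygosity 2p(1-p)n/(n-1) for one population;
# sites with fewer than 2 called diploids contribute NA
site_heterozygosity <- function(gm, cols) {
  st <- site_allele_stats(gm, cols)
  h <- ifelse(st$n_dip >= 2,
              2 * st$p * (1 - st$p) * st$an / (st$an - 1), NA_real_)
  h
}

#' Windowed nucleotide diversity
#'
#' Per-window pi is the sum over sites of the unbiased per-site
#' heterozygosity 2p(1-p) n/(n-1) (n = non-missing allele count), divided by
#' the window length in bp. Windows with fewer SNPs than `min_snps` are
#' emitted with the statistic set to NA rather than dropped, so grids stay
#' aligned across populations.
#'
#' @param gm a [geno_matrix()].
#' @param pop population label(s) defining the accession set.
#' @param window,step window grid in bp (see [make_windows()]).
#' @param min_snps minimum informative SNPs for a window estimate.
#' @param chrom_len chromosome lengths; defaults to `gm$chrom_len` or the
#'   maximum observed position.
#' @return window table (chrom, start, end, n_snps, pi).
#' @export
window_pi <- function(gm, pop, window = 5e5, step = 1.25e5, min_snps = 5,
                      chrom_len = NULL) {
  cols <- pop_cols(gm, pop)
  if (is.null(chrom_len)) chrom_len <- gm_chrom_len(gm)
  wt <- make_windows(chrom_len, window, step)
  h <- site_heterozygosity(gm, cols)
  agg <- window_aggregate(gm, wt, h)
  wt$n_snps <- agg$n
  wt$pi <- ifelse(agg$n >= min_snps, agg$sum / (wt$end - wt$start), NA_real_)
  wt
}

gm_chrom_len <- function(gm) {
  if (!is.null(gm$chrom_len)) return(gm$chrom_len)
  tapply(gm$pos, gm$chrom, max)
}

# sum a per-site quantity over a (possibly sliding) window grid; counts use
# non-NA sites. Windows are 0-based half-open over 1-based site positions.
window_aggregate <- function(gm, wt, x) {
  n <- numeric(nrow(wt)); s <- numeric(nrow(wt))
  pos0 <- gm$pos - 1L
  for (ch in unique(wt$chrom)) {
    wi <- which(wt$chrom == ch)
    si <- which(gm$chrom == ch & !is.na(x))
    if (!length(si)) next
    for (j in wi) {
      sel <- si[pos0[si] >= wt$start[j] & pos0[si] < wt$end[j]]
      n[j] <- length(sel)
      s[j] <- sum(x[sel])
    }
  }
  list(n = n, sum = s)
}

#' Genome-wide (windowless) nucleotide diversity
#'
#' Mean per-bp diversity over the full analyzed length: the sum of per-site
#' unbiased heterozygosity divided by total bp. Appropriate for sparse
#' reduced-representation SNP sets where most windows would hold too few
#' SNPs for a stable windowed estimate.
#'
#' @param gm a [geno_matrix()].
#' @param pop population label(s).
#' @param total_bp analyzed genome length in bp (defaults to the sum of
#'   chromosome lengths).
#' @return scalar pi per bp.
#' @export
windowless_pi <- function(gm, pop, total_bp = NULL) {
  cols <- pop_cols(gm, pop)
  if (is.null(total_bp)) total_bp <- sum(gm_chrom_len(gm))
  if (is.null(total_bp) || total_bp <= 0) stop("analyzed length must be positive")
  h <- site_heterozygosity(gm, cols)
  sum(h, na.rm = TRUE) / total_bp
}

# Weir & Cockerham (1984) per-site variance components for two populations,
# from sample sizes (diploids), allele frequencies and observed
# heterozygosity. Returns the a (among-population), b (among individuals
# within populations) and c (within individuals) components.
wc84_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

# Hudson estimator per-site numerator/denominator (Bhatia et al. 2013 form),
# from allele counts
hudson_components <- function(an1, p1, an2, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (an1 - 1) - p2 * (1 - p2) / (an2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  list(num = num, den = den)
}

#' Pairwise fixation index between two populations
#'
#' Weir & Cockerham's (1984) weighted (ratio-of-sums) estimator by default,
#' with Hudson's estimator available as a cross-check. Returns either a
#' genome-wide scalar or a windowed table. Negative window estimates are
#' clamped to 0 in the `fst` column (keeping the later log(1 - FST)
#' branch-length transform defined), with the raw value retained in
#' `fst_raw`. Sites where either population has fewer than 2 called diploids
#' are skipped.
#'
#' @param gm a [geno_matrix()].
#' @param popA,popB disjoint population labels, each with >= 2 accessions.
#' @param windows NULL for a genome-wide scalar, or "grid" for the window
#'   grid given by `window`/`step`, or a precomputed window data.frame.
#' @param estimator "wc" (Weir-Cockerham 1984) or "hudson".
#' @param window,step,min_snps window grid parameters.
#' @param chrom_len chromosome lengths (defaults from the object).
#' @return scalar FST, or window table with n_snps, fst, fst_raw.
#' @export
pairwise_fst <- function(gm, popA, popB, windows = NULL,
                         estimator = c("wc", "hudson"),
                         window = 5e5, step = 1.25e5, min_snps = 5,
                         chrom_len = NULL) {
  estimator <- match.arg(estimator)
  colsA <- pop_cols(gm, popA); colsB <- pop_cols(gm, popB)
  if (length(intersect(colsA, colsB)))
    stop("populations must be disjoint")
  if (length(colsA) < 2 || length(colsB) < 2)
    stop("each population needs at least 2 accessions")
  stA <- site_allele_stats(gm, colsA); stB <- site_allele_stats(gm, colsB)
  ok <- stA$n_dip >= 2 & stB$n_dip >= 2
  if (estimator == "wc") {
    comp <- wc84_components(stA$n_dip, stA$p, stA$n_het / stA$n_dip,
                            stB$n_dip, stB$p, stB$n_het / stB$n_dip)
    num <- comp$a
    den <- comp$a + comp$b + comp$c
  } else {
    comp <- hudson_components(stA$an, stA$p, stB$an, stB$p)
    num <- comp$num
    den <- comp$den
  }
  num[!ok] <- NA_real_; den[!ok] <- NA_real_
  if (is.null(windows)) {
    return(sum(num, na.rm = TRUE) / sum(den, na.rm = TRUE))
  }
  wt <- if (is.data.frame(windows)) windows else {
    if (is.null(chrom_len)) chrom_len <- gm_chrom_len(gm)
    make_windows(chrom_len, window, step)
  }
  informative <- !is.na(den) & den > 0
  x <- ifelse(informative, num, NA_real_)
  agg_num <- window_aggregate(gm, wt, x)
  y <- ifelse(informative, den, NA_real_)
  agg_den <- window_aggregate(gm, wt, y)
  wt$n_snps <- agg_num$n
  raw <- ifelse(agg_num$n >= min_snps & agg_den$sum > 0,
                agg_num$sum / agg_den$sum, NA_real_)
  wt$fst <- pmax(raw, 0)
  wt$fst_raw <- raw
  wt
}

#' Per-generation mutation rate from synonymous divergence
#'
#' mu = Ks / (2 T): synonymous substitutions accumulate along both lineages
#' since the split, so the per-lineage per-year rate is the synonymous
#' divergence over twice the divergence time.
#'
#' @param ks synonymous divergence between the two species (> 0).
#' @param divergence_time_years split time T in years (> 0).
#' @return mutation rate per site per year.
#' @export
mutation_rate <- function(ks, divergence_time_years) {
  if (!is.numeric(ks) || ks <= 0) stop("ks must be positive")
  if (!is.numeric(divergence_time_years) || divergence_time_years <= 0)
    stop("divergence time must be positive")
  ks / (2 * divergence_time_years)
}
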