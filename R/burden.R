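#' Call deleterious sites from functional-impact scores
#'
#' A site is deleterious when its SIFT-scale score is less than or equal to
#' the threshold (0.05 by convention, boundary inclusive) and tolerated
#' otherwise.
#'
#' @param score_table data.frame with chrom, pos, score (scores in [0, 1]).
#' @param threshold deleterious score cutoff.
#' @return the table with a logical `deleterious` column.
#' @export
call_deleterious <- function(score_table, threshold = 0.05) {
  s <- score_table$score
  if (any(is.na(s)) || any(s < 0) || any(s > 1))
    stop("scores must lie in [0, 1]")
  score_table$deleterious <- s <= threshold
  score_table
}

#' Per-accession deleterious burden profiles
#'
#' For each accession, the deleterious sites it carries, split by zygosity:
#' a homozygous-derived genotype (2) is a homozygous deleterious mutation, a
#' heterozygous genotype (1) a heterozygous one; homozygous-reference and
#' missing genotypes carry nothing.
#'
#' @param gm a [geno_matrix()].
#' @param deleterious_sites data.frame with chrom, pos of deleterious sites
#'   (e.g. the flagged rows of [call_deleterious()]); must be a subset of
#'   the matrix sites.
#' @return object of class `burden_profiles`: the deleterious-site genotype
#'   submatrix plus accession metadata. `summary()` gives per-accession
#'   n_hom, n_het, n_total.
#' @export
burden_profiles <- function(gm, deleterious_sites) {
  key <- paste(gm$chrom, gm$pos)
  want <- paste(deleterious_sites$chrom, deleterious_sites$pos)
  idx <- match(want, key)
  if (anyNA(idx)) stop("deleterious sites not present in the genotype matrix")
  structure(list(site_id = key[idx],
                 chrom = gm$chrom[idx], pos = gm$pos[idx],
                 geno = gm$geno[idx, , drop = FALSE],
                 samples = gm$samples, pops = gm$pops),
            class = "burden_profiles")
}

#' @export
summary.burden_profiles <- function(object, ...) {
  g <- object$geno
  data.frame(accession = object$samples, group = object$pops,
             n_hom = as.integer(colSums(g == 2L, na.rm = TRUE)),
             n_het = as.integer(colSums(g == 1L, na.rm = TRUE)),
             n_total = as.integer(colSums(g >= 1L, na.rm = TRUE)),
             row.names = NULL)
}

#' @export
print.burden_profiles <- function(x, ...) {
  s <- summary(x)
  cat("burden_profiles:", length(x$site_id), "deleterious sites,",
      length(x$samples), "accessions\n")
  cat(sprintf("  mean burden: %.1f (%.1f hom + %.1f het)\n",
              mean(s$n_total), mean(s$n_hom), mean(s$n_het)))
  invisible(x)
}

#' Pairwise burden overlap ratio
#'
#' Allele-sharing score for the deleterious mutations of two accessions:
#' over the sites carried by both, a counts pairs where both are homozygous
#' derived, b pairs where one is homozygous and the other heterozygous, and
#' c pairs where both are heterozygous; d is the number of distinct
#' deleterious sites carried by either accession. The ratio
#' (a + 0.5 b + 0.25 c) / d weights each shared site by the probability
#' that alleles drawn from the two accessions match, and equals 1 exactly
#' for identical all-homozygous profiles.
#'
#' @param profiles a [burden_profiles()] object.
#' @param accA,accB accession ids (or column indices).
#' @return overlap ratio in [0, 1]; 0 (with a warning) when neither
#'   accession carries any deleterious site.
#' @export
overlap_ratio <- function(profiles, accA, accB) {
  ga <- burden_col(profiles, accA)
  gb <- burden_col(profiles, accB)
  carA <- !is.na(ga) & ga >= 1L
  carB <- !is.na(gb) & gb >= 1L
  both <- carA & carB
  a <- sum(ga[both] == 2L & gb[both] == 2L)
  b <- sum((ga[both] == 2L & gb[both] == 1L) |
             (ga[both] == 1L & gb[both] == 2L))
  cc <- sum(ga[both] == 1L & gb[both] == 1L)
  d <- sum(carA | carB)
  if (d == 0) {
    warning("neither accession carries a deleterious site; ratio set to 0")
    return(0)
  }
  (a + 0.5 * b + 0.25 * cc) / d
}

burden_col <- function(profiles, acc) {
  if (is.character(acc)) {
    j <- match(acc, profiles$samples)
    if (is.na(j)) stop("unknown accession: ", acc)
  } else j <- acc
  profiles$geno[, j]
}

#' Pairwise burden overlap matrix with group summaries
#'
#' @param profiles a [burden_profiles()] object with >= 2 accessions.
#' @return list with `matrix` (symmetric accession x accession overlap
#'   ratios, unit diagonal-free NA) and `group_summary` (mean/median ratio
#'   for within-group and between-group pairs).
#' @export
overlap_matrix <- function(profiles) {
  n <- length(profiles$samples)
  if (n < 2) stop("need at least 2 accessions")
  m <- matrix(NA_real_, n, n,
              dimnames = list(profiles$samples, profiles$samples))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- suppressWarnings(overlap_ratio(profiles, i, j))
      m[i, j] <- m[j, i] <- r
    }
  }
  pair <- which(upper.tri(m), arr.ind = TRUE)
  within <- profiles$pops[pair[, 1]] == profiles$pops[pair[, 2]]
  vals <- m[pair]
  group_summary <- data.frame(
    pair_type = c("within", "between"),
    n_pairs = c(sum(within), sum(!within)),
    mean = c(mean(vals[within]), mean(vals[!within])),
    median = c(median(vals[within]), median(vals[!within])))
  list(matrix = m, group_summary = group_summary)
}

#' Sweep-based removal and density of deleterious mutations
#'
#' Quantifies purging of deleterious variation in a derived (cultivated)
#' group relative to a reference (origin) group. A reference deleterious
#' site is "removed" when no derived-group accession carries it. Removal is
#' reported genome-wide and inside the sweep regions. The density of
#' derived-group deleterious sites (sites per Mb) is compared between sweep
#' regions and control regions (all non-overlapping windows of the same
#' grid that do not touch a sweep) with a two-sided Mann-Whitney U test.
#'
#' @param profiles a [burden_profiles()] object holding both groups.
#' @param ref_group,derived_group population labels.
#' @param sweeps sweep-region table (chrom, start, end, 0-based half-open).
#' @param chrom_len named chromosome lengths for the control-window grid.
#' @param window control/sweep grid window size in bp.
#' @return list with removed_pct_genome, removed_pct_sweep, density table
#'   (per-region densities), mean densities, pct_fewer_in_sweeps and the
#'   Mann-Whitney p-value.
#' @export
sweep_removal <- function(profiles, ref_group, derived_group, sweeps,
                          chrom_len, window = 5e5) {
  if (!nrow(sweeps)) stop("no sweep regions supplied")
  ref_cols <- which(profiles$pops %in% ref_group)
  der_cols <- which(profiles$pops %in% derived_group)
  if (!length(ref_cols) || !length(der_cols))
    stop("reference or derived group not found")
  g <- profiles$geno
  carried_ref <- rowSums(g[, ref_cols, drop = FALSE] >= 1L, na.rm = TRUE) > 0
  carried_der <- rowSums(g[, der_cols, drop = FALSE] >= 1L, na.rm = TRUE) > 0
  removed <- carried_ref & !carried_der
  in_sweep <- rep(FALSE, length(profiles$pos))
  for (ch in unique(sweeps$chrom)) {
    si <- profiles$chrom == ch
    sw <- sweeps[sweeps$chrom == ch, ]
    if (!any(si) || !nrow(sw)) next
    in_sweep[si] <- IRanges::overlapsAny(
      IRanges::IRanges(profiles$pos[si], width = 1),
      IRanges::IRanges(sw$start + 1L, sw$end))
  }
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  removed_pct_genome <- pct(sum(removed & carried_ref), sum(carried_ref))
  removed_pct_sweep <- pct(sum(removed & carried_ref & in_sweep),
                           sum(carried_ref & in_sweep))
  # per-region derived-group deleterious density (sites per Mb)
  grid <- make_windows(chrom_len, window = window, step = window)
  ctrl <- grid[!region_overlaps(grid, sweeps), , drop = FALSE]
  dens <- function(regions) {
    vapply(seq_len(nrow(regions)), function(i) {
      ch <- regions$chrom[i]
      nsites <- sum(profiles$chrom == ch & carried_der &
                      profiles$pos > regions$start[i] &
                      profiles$pos <= regions$end[i])
      nsites / ((regions$end[i] - regions$start[i]) / 1e6)
    }, numeric(1))
  }
  d_sweep <- dens(sweeps)
  d_ctrl <- dens(ctrl)
  mw <- suppressWarnings(wilcox.test(d_sweep, d_ctrl, exact = FALSE))
  list(removed_pct_genome = removed_pct_genome,
       removed_pct_sweep = removed_pct_sweep,
       density_sweep = d_sweep, density_control = d_ctrl,
       mean_density_sweep = mean(d_sweep),
       mean_density_control = mean(d_ctrl),
       pct_fewer_in_sweeps =
         if (mean(d_ctrl) > 0) 100 * (1 - mean(d_sweep) / mean(d_ctrl))
         else NA_real_,
       mann_whitney_p = mw$p.value)
}

region_overlaps <- function(regions, other) {
  hit <- rep(FALSE, nrow(regions))
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    ot <- other[other$chrom == ch, , drop = FALSE]
    if (!nrow(ot)) next
    hit[ri] <- IRanges::overlapsAny(
      IRanges::IRanges(regions$start[ri] + 1L, regions$end[ri]),
      IRanges::IRanges(ot$start + 1L, ot$end))
  }
  hit
}

#' Rare deleterious fraction
#'
#' Fraction of deleterious sites whose derived-allele frequency across all
#' accessions is at or below `max_freq`.
#'
#' @param profiles a [burden_profiles()] object.
#' @param max_freq frequency cutoff defining "rare".
#' @return percentage (0-100).
#' @export
rare_deleterious_pct <- function(profiles, max_freq = 0.05) {
  g <- profiles$geno
  an <- 2 * rowSums(!is.na(g))
  p <- rowSums(g, na.rm = TRUE) / an
  100 * mean(p[an > 0] <= max_freq)
}
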