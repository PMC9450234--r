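#' Bonferroni association threshold
#'
#' alpha / n_markers, reported at `sig_digits` significant figures (3 by
#' default, matching how genome-wide thresholds are usually quoted). Pass an
#' effective number of independent markers as `n_markers` when linkage makes
#' the full marker count overly conservative.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_markers number of (effective) markers tested (>= 1).
#' @param sig_digits significant figures for reporting; NULL for the exact
#'   value.
#' @return per-marker P threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_markers, sig_digits = 3) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (!is.numeric(n_markers) || n_markers < 1)
    stop("n_markers must be >= 1")
  thr <- alpha / n_markers
  if (is.null(sig_digits)) thr else signif(thr, sig_digits)
}

#' Genes near association signals
#'
#' Lists every gene whose span lies within `max_dist` bp of a signal: the
#' distance is 0 for a SNP inside the gene and otherwise the distance to
#' the nearest gene edge, strand-ignored.
#'
#' @param signals data.frame with chrom, pos (1-based), and optionally
#'   trait and p columns.
#' @param gene_model gene-model data.frame (1-based inclusive).
#' @param max_dist maximum SNP-to-gene distance in bp (inclusive).
#' @return data.frame of signal x gene pairs with the distance.
#' @export
nearby_genes <- function(signals, gene_model, max_dist = 2e5) {
  genes <- gene_model[if ("type" %in% names(gene_model))
    gene_model$type == "gene" else TRUE, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(signals))) {
    g <- genes[genes$chrom == signals$chrom[i], , drop = FALSE]
    if (!nrow(g)) next
    pos <- signals$pos[i]
    dist <- ifelse(pos >= g$start & pos <= g$end, 0,
                   pmin(abs(pos - g$start), abs(pos - g$end)))
    keep <- dist <= max_dist
    if (!any(keep)) next
    out[[length(out) + 1]] <- data.frame(
      chrom = signals$chrom[i], pos = pos,
      trait = if ("trait" %in% names(signals)) signals$trait[i] else NA,
      gene_id = g$gene_id[keep], distance = dist[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chrom = character(), pos = integer(),
                      trait = character(), gene_id = character(),
                      distance = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Overlap of association signals with sweep regions
#'
#' A signal overlaps when its position, widened by `flank` bp on each side,
#' intersects a sweep interval (0-based half-open).
#'
#' @param signals data.frame with chrom, pos (1-based).
#' @param sweeps sweep-region table (chrom, start, end).
#' @param flank bp added on both sides of each signal.
#' @return `signals` with a logical `in_sweep` column.
#' @export
signal_sweep_overlap <- function(signals, sweeps, flank = 0) {
  hit <- rep(FALSE, nrow(signals))
  for (ch in unique(signals$chrom)) {
    si <- which(signals$chrom == ch)
    sw <- sweeps[sweeps$chrom == ch, , drop = FALSE]
    if (!nrow(sw)) next
    hit[si] <- IRanges::overlapsAny(
      IRanges::IRanges(pmax(1L, signals$pos[si] - flank),
                       signals$pos[si] + flank),
      IRanges::IRanges(sw$start + 1L, sw$end))
  }
  signals$in_sweep <- hit
  signals
}
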