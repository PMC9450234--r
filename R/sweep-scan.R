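#' Population branch statistic
#'
#' PBS for a target population TP against a control population CP and an
#' outgroup CO, from the three pairwise FST values. Each FST is transformed
#' to a divergence-time branch length T = -ln(1 - FST), and the target
#' branch is isolated as
#' PBS = (T_TP,CP + T_TP,CO - T_CP,CO) / 2.
#' Elevated values indicate lineage-specific allele-frequency change in the
#' target population; negative values are possible and meaningful (shared
#' control/outgroup divergence exceeding the target branch).
#'
#' FST values below 0 are clamped to 0 and values of 1 are clamped to
#' 1 - 1e-12 (with a warning) to keep the log transform finite. Vectorized
#' over windows.
#'
#' @param fst_tp_cp FST between target and control population.
#' @param fst_tp_co FST between target population and outgroup.
#' @param fst_cp_co FST between control population and outgroup.
#' @return PBS value(s).
#' @export
pbs <- function(fst_tp_cp, fst_tp_co, fst_cp_co) {
  clamp <- function(f) {
    if (any(f >= 1, na.rm = TRUE)) {
      warning("FST of 1 clamped to 1 - 1e-12")
      f <- pmin(f, 1 - 1e-12)
    }
    pmax(f, 0)
  }
  t1 <- -log(1 - clamp(fst_tp_cp))
  t2 <- -log(1 - clamp(fst_tp_co))
  t3 <- -log(1 - clamp(fst_cp_co))
  (t1 + t2 - t3) / 2
}

#' Windowed PBS scan with Z-test outlier flagging
#'
#' Computes per-window PBS from three aligned windowed FST columns, then
#' standardizes over all non-missing windows and flags windows whose
#' one-sided Z-test is significant at `alpha` (selection elevates PBS, so
#' only the upper tail is tested and negative-PBS windows are never
#' flagged).
#'
#' @param windows data.frame of aligned windows carrying the three FST
#'   columns named in `fst_cols`.
#' @param fst_cols length-3 character vector naming the columns for
#'   FST(TP,CP), FST(TP,CO), FST(CP,CO), in that order.
#' @param alpha one-sided significance level.
#' @param min_windows minimum non-missing windows for the Z reference.
#' @return the window table with pbs, pbs_z and logical `selected` added.
#' @export
pbs_scan <- function(windows, fst_cols = c("fst_tp_cp", "fst_tp_co",
                                           "fst_cp_co"),
                     alpha = 0.05, min_windows = 30) {
  stopifnot(all(fst_cols %in% names(windows)))
  p <- pbs(windows[[fst_cols[1]]], windows[[fst_cols[2]]],
           windows[[fst_cols[3]]])
  ok <- !is.na(p)
  if (sum(ok) < min_windows)
    stop("need at least ", min_windows, " non-missing windows")
  s <- sd(p[ok])
  if (s == 0) {
    warning("PBS has zero variance across windows; no window flagged")
    z <- ifelse(is.na(p), NA_real_, 0)
  } else {
    z <- (p - mean(p[ok])) / s
  }
  windows$pbs <- p
  windows$pbs_z <- z
  windows$selected <- !is.na(z) & z > qnorm(1 - alpha)
  windows
}

# nearest-rank quantile threshold: value at rank ceil(q * m) of the sorted
# vector; ties at the threshold are included by the callers
nearest_rank <- function(x, q, lower = TRUE) {
  x <- sort(x)
  m <- length(x)
  k <- max(1L, ceiling(q * m))
  if (lower) x[k] else x[m - k + 1L]
}

#' log2 diversity-ratio scan
#'
#' For aligned window grids of nucleotide diversity in populations A and B,
#' computes log2(pi_A / pi_B) where both are positive, and flags the bottom
#' `tail` fraction (unusually negative: selection reduced diversity in A)
#' and the top `tail` fraction (selection in B). Quantiles use the
#' nearest-rank method; ties at the threshold are all included. Windows with
#' zero or missing diversity are excluded from the quantile computation and
#' never flagged.
#'
#' @param piA,piB window tables from [window_pi()] on the same grid.
#' @param tail outlier fraction per tail.
#' @return the window grid with log2_ratio, selected_A and selected_B.
#' @export
pi_ratio_scan <- function(piA, piB, tail = 0.05) {
  if (nrow(piA) != nrow(piB) ||
      !all(piA$chrom == piB$chrom & piA$start == piB$start &
           piA$end == piB$end))
    stop("window grids are not aligned")
  out <- piA[, c("chrom", "start", "end")]
  ratio <- ifelse(!is.na(piA$pi) & !is.na(piB$pi) &
                    piA$pi > 0 & piB$pi > 0,
                  log2(piA$pi / piB$pi), NA_real_)
  out$log2_ratio <- ratio
  ok <- !is.na(ratio)
  if (!any(ok)) {
    out$selected_A <- out$selected_B <- rep(FALSE, nrow(out))
    return(out)
  }
  lo <- nearest_rank(ratio[ok], tail, lower = TRUE)
  hi <- nearest_rank(ratio[ok], tail, lower = FALSE)
  out$selected_A <- ok & ratio <= lo
  out$selected_B <- ok & ratio >= hi
  out
}

#' Load externally computed XP-CLR window scores
#'
#' Reads a TSV of per-window cross-population composite-likelihood-ratio
#' scores (computed by an external scanner) and flags the top `tail`
#' fraction by score (nearest-rank quantile, ties inclusive).
#'
#' @param path TSV with columns chrom, start, end, score (0-based half-open
#'   windows), or a data.frame of the same shape.
#' @param tail outlier fraction.
#' @return window table with logical `selected`.
#' @export
load_xpclr <- function(path, tail = 0.05) {
  df <- if (is.data.frame(path)) path else {
    first <- tryCatch(readLines(path, n = 1), error = function(e) character())
    if (!length(first))
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), score = numeric(),
                        selected = logical()))
    read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  need <- c("chrom", "start", "end", "score")
  if (!all(need %in% names(df)))
    stop("XP-CLR table must have columns chrom, start, end, score")
  if (!nrow(df)) {
    df$selected <- logical()
    return(df)
  }
  if (!is.numeric(df$score) || anyNA(df$score))
    stop("malformed XP-CLR rows: non-numeric or missing scores")
  thr <- nearest_rank(df$score, tail, lower = FALSE)
  df$selected <- df$score >= thr
  df
}

#' Consensus selective-sweep calling across scan methods
#'
#' Projects each method's flagged windows onto base pairs (methods may use
#' different window grids), counts at every bp how many methods flag it, and
#' returns the maximal runs supported by at least `min_support` methods as
#' merged sweep regions. Every returned region therefore lies inside the
#' union of flagged bp, and raising `min_support` never enlarges a region.
#'
#' @param flagged named list of window tables, each with chrom, start, end
#'   (0-based half-open) and a logical flag column (`selected` by default;
#'   set per-table via `flag_cols`).
#' @param min_support minimum number of supporting methods.
#' @param flag_cols optional named character vector mapping table name to
#'   its flag column (e.g. `c(piratio = "selected_A")`).
#' @return data.frame of sweep regions (chrom, start, end, supporters,
#'   n_methods) with 0-based half-open merged intervals.
#' @export
consensus_sweeps <- function(flagged, min_support = 2, flag_cols = NULL) {
  if (length(flagged) < 2) stop("at least two methods are required")
  if (is.null(names(flagged)))
    names(flagged) <- paste0("method", seq_along(flagged))
  per_method <- lapply(names(flagged), function(nm) {
    df <- flagged[[nm]]
    col <- if (!is.null(flag_cols) && nm %in% names(flag_cols))
      flag_cols[[nm]] else "selected"
    if (!col %in% names(df)) stop("no flag column '", col, "' in ", nm)
    df[df[[col]] %in% TRUE, c("chrom", "start", "end"), drop = FALSE]
  })
  names(per_method) <- names(flagged)
  chroms <- sort(unique(unlist(lapply(per_method, function(d) d$chrom))))
  out <- list()
  for (ch in chroms) {
    irs <- lapply(per_method, function(d) {
      dd <- d[d$chrom == ch, , drop = FALSE]
      IRanges::reduce(IRanges::IRanges(dd$start + 1L, dd$end))
    })
    width <- max(1L, unlist(lapply(irs, function(ir)
      if (length(ir)) max(IRanges::end(ir)) else 0L)))
    cov <- Reduce(`+`, lapply(irs, IRanges::coverage, width = width))
    sl <- IRanges::slice(cov, lower = min_support, rangesOnly = TRUE)
    sl <- IRanges::reduce(sl)
    if (!length(sl)) next
    supporters <- vapply(seq_along(sl), function(i) {
      hit <- vapply(irs, function(ir)
        any(IRanges::overlapsAny(sl[i], ir)), logical(1))
      paste(names(irs)[hit], collapse = ",")
    }, "")
    out[[ch]] <- data.frame(chrom = ch,
                            start = IRanges::start(sl) - 1L,
                            end = IRanges::end(sl),
                            supporters = supporters,
                            n_methods = lengths(strsplit(supporters, ",")))
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), supporters = character(),
                      n_methods = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assign genes to sweep regions
#'
#' A gene is listed for a region when its span overlaps the region by at
#' least 1 bp (regions are 0-based half-open; gene models 1-based
#' inclusive).
#'
#' @param sweeps sweep-region data.frame from [consensus_sweeps()].
#' @param gene_model gene-model data.frame.
#' @return `sweeps` with a `genes` list-column of gene ids.
#' @export
assign_genes <- function(sweeps, gene_model) {
  genes <- gene_model[if ("type" %in% names(gene_model))
    gene_model$type == "gene" else TRUE, , drop = FALSE]
  res <- vector("list", nrow(sweeps))
  for (ch in unique(sweeps$chrom)) {
    si <- which(sweeps$chrom == ch)
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (!nrow(g)) { res[si] <- list(character()); next }
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sweeps$start[si] + 1L, sweeps$end[si]),
      IRanges::IRanges(g$start, g$end))
    for (k in seq_along(si)) {
      hits <- S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == k]
      res[[si[k]]] <- g$gene_id[hits]
    }
  }
  sweeps$genes <- res
  sweeps
}

#' Intersect two sweep sets
#'
#' Regions selected in both populations (interval intersection) and the
#' genes shared between the two sweep gene sets.
#'
#' @param sweepsA,sweepsB sweep tables (with `genes` list-columns when the
#'   shared gene set is wanted).
#' @return list with `regions` (chrom, start, end of the intersection) and
#'   `shared_genes`.
#' @export
shared_sweeps <- function(sweepsA, sweepsB) {
  chroms <- intersect(sweepsA$chrom, sweepsB$chrom)
  regions <- list()
  for (ch in chroms) {
    a <- sweepsA[sweepsA$chrom == ch, ]
    b <- sweepsB[sweepsB$chrom == ch, ]
    inter <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(a$start + 1L, a$end)),
      IRanges::reduce(IRanges::IRanges(b$start + 1L, b$end)))
    if (length(inter))
      regions[[ch]] <- data.frame(chrom = ch,
                                  start = IRanges::start(inter) - 1L,
                                  end = IRanges::end(inter))
  }
  regions <- if (length(regions)) do.call(rbind, regions)
  else data.frame(chrom = character(), start = integer(), end = integer())
  rownames(regions) <- NULL
  shared_genes <- if (!is.null(sweepsA$genes) && !is.null(sweepsB$genes))
    intersect(unlist(sweepsA$genes), unlist(sweepsB$genes)) else NULL
  list(regions = regions, shared_genes = shared_genes)
}

#' Patterson's D statistic (ABBA-BABA) with block jackknife
#'
#' Frequency-based D for unphased diploid data: with derived-allele
#' frequencies p1..p3 in populations P1, P2, P3 and p4 in the outgroup,
#' ABBA = sum (1-p1) p2 p3 (1-p4) and BABA = sum p1 (1-p2) p3 (1-p4), and
#' D = (ABBA - BABA) / (ABBA + BABA). Under no gene flow between P3 and
#' P1/P2, E[D] = 0. Significance comes from a delete-one block jackknife
#' over contiguous genomic blocks of `block_bp`.
#'
#' @param gm a [geno_matrix()].
#' @param P1,P2,P3,outgroup disjoint population labels; the outgroup
#'   polarizes the test through its derived frequency p4.
#' @param block_bp jackknife block size in bp.
#' @return object of class `d_stat`: list(D, Z, n_blocks, abba, baba).
#' @export
patterson_d <- function(gm, P1, P2, P3, outgroup, block_bp = 1e6) {
  labs <- list(P1, P2, P3, outgroup)
  cols <- lapply(labs, function(p) pop_cols(gm, p))
  if (anyDuplicated(unlist(cols)))
    stop("P1, P2, P3 and outgroup must be disjoint")
  p <- lapply(cols, function(cl) site_allele_stats(gm, cl)$p)
  ok <- !Reduce(`|`, lapply(p, is.na))
  abba_s <- (1 - p[[1]]) * p[[2]] * p[[3]] * (1 - p[[4]])
  baba_s <- p[[1]] * (1 - p[[2]]) * p[[3]] * (1 - p[[4]])
  abba_s[!ok] <- NA_real_; baba_s[!ok] <- NA_real_
  abba <- sum(abba_s, na.rm = TRUE)
  baba <- sum(baba_s, na.rm = TRUE)
  if (abba + baba == 0) stop("no informative sites (ABBA + BABA = 0)")
  D <- (abba - baba) / (abba + baba)
  block <- paste(gm$chrom, floor((gm$pos - 1) / block_bp))
  informative <- ok & (abba_s + baba_s) > 0
  blocks <- unique(block[informative])
  if (length(blocks) < 2)
    stop("need at least 2 non-empty blocks for a jackknife Z-score")
  d_jack <- vapply(blocks, function(b) {
    keep <- block != b
    (sum(abba_s[keep], na.rm = TRUE) - sum(baba_s[keep], na.rm = TRUE)) /
      (sum(abba_s[keep], na.rm = TRUE) + sum(baba_s[keep], na.rm = TRUE))
  }, numeric(1))
  B <- length(blocks)
  se <- sqrt((B - 1) / B * sum((d_jack - mean(d_jack))^2))
  structure(list(D = D, Z = if (se > 0) D / se else NA_real_,
                 n_blocks = B, abba = abba, baba = baba),
            class = "d_stat")
}

#' @export
print.d_stat <- function(x, ...) {
  cat(sprintf("Patterson's D = %.4f (Z = %.2f, %d blocks; ABBA = %.1f, BABA = %.1f)\n",
              x$D, x$Z, x$n_blocks, x$abba, x$baba))
  invisible(x)
}

#' Write sweep regions as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal
#' representation, so intervals are written verbatim.
#'
#' @param sweeps sweep table.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sweeps_bed <- function(sweeps, path) {
  df <- data.frame(sweeps$chrom, sweeps$start, sweeps$end,
                   if (!is.null(sweeps$supporters)) sweeps$supporters else ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
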