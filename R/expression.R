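#' FPKM from fragment counts
#'
#' counts * 1e9 / (gene_length_bp * library_size): fragments per kilobase of
#' transcript per million mapped fragments.
#'
#' @param counts fragment counts (vectorized).
#' @param gene_length_bp transcript length in bp (> 0).
#' @param library_size total mapped fragments in the library (> 0).
#' @return FPKM values.
#' @export
fpkm <- function(counts, gene_length_bp, library_size) {
  if (any(gene_length_bp <= 0)) stop("gene length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  counts * 1e9 / (gene_length_bp * library_size)
}

#' Group differential expression by one-way ANOVA with BH correction
#'
#' Per gene, a one-way analysis of variance of abundance across the groups
#' (for two groups this is the equal-variance t-test in F form). P values
#' are corrected over all tested genes with the Benjamini-Hochberg
#' procedure; genes with q below `q_threshold` are called differentially
#' expressed. Genes with zero variance across accessions get P = 1 by
#' convention.
#'
#' @param expr genes x accessions abundance matrix.
#' @param groups group label per accession (>= 2 groups, >= 3 accessions
#'   per group).
#' @param q_threshold FDR cutoff for the DE call.
#' @return data.frame (gene, f, p, q, de).
#' @export
group_de <- function(expr, groups, q_threshold = 0.05) {
  groups <- as.factor(as.character(groups))
  stopifnot(ncol(expr) == length(groups))
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 3)) stop("need at least 3 accessions per group")
  k <- nlevels(groups)
  n <- ncol(expr)
  gmeans <- vapply(levels(groups), function(g)
    rowMeans(expr[, groups == g, drop = FALSE]), numeric(nrow(expr)))
  sizes <- as.numeric(table(groups))[match(levels(groups), names(table(groups)))]
  grand <- rowMeans(expr)
  ss_between <- as.numeric(
    (gmeans - grand)^2 %*% sizes)
  ss_total <- rowSums((expr - grand)^2)
  ss_within <- ss_total - ss_between
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero_var <- ss_total < .Machine$double.eps * n
  p[zero_var] <- 1
  f[zero_var] <- 0
  # within-group-constant but between-group-different genes have
  # ss_within ~ 0 and infinite F: P -> 0
  p[!zero_var & !is.finite(f)] <- 0
  q <- p.adjust(p, method = "BH")
  data.frame(gene = rownames(expr), f = f, p = p, q = q,
             de = q < q_threshold, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Expression gain/loss classification between two groups
#'
#' A gene "emerges expression" (EE) in the derived group when no reference
#' accession shows any transcript (abundance exactly 0 in all) and it is
#' expressed (> 0) in more than `presence_frac` of derived accessions. The
#' symmetric rule (expressed in more than `presence_frac` of reference
#' accessions, zero in all derived) classifies it as "loses expression"
#' (LE).
#'
#' @param expr genes x accessions abundance matrix.
#' @param groups group label per accession.
#' @param ref_group,derived_group the two groups compared.
#' @param presence_frac strict presence-fraction threshold (default 0.9).
#' @return character vector per gene: "EE", "LE" or "none".
#' @export
classify_gain_loss <- function(expr, groups, ref_group, derived_group,
                               presence_frac = 0.9) {
  ref <- expr[, groups == ref_group, drop = FALSE]
  der <- expr[, groups == derived_group, drop = FALSE]
  if (!ncol(ref)) stop("reference group is empty")
  if (!ncol(der)) stop("derived group is empty")
  ref_silent <- rowSums(ref > 0) == 0
  der_silent <- rowSums(der > 0) == 0
  ref_present <- rowMeans(ref > 0) > presence_frac
  der_present <- rowMeans(der > 0) > presence_frac
  out <- rep("none", nrow(expr))
  out[ref_silent & der_present] <- "EE"
  out[ref_present & der_silent] <- "LE"
  names(out) <- rownames(expr)
  out
}

#' Full expression-evolution classification for one group pair
#'
#' Combines gain/loss calls and the ANOVA DE test: EE and LE take
#' precedence; remaining genes are DE when significant at the FDR cutoff
#' and expressed in both groups, and NS otherwise. The classes are mutually
#' exclusive and cover every tested gene.
#'
#' @param expr genes x accessions abundance matrix.
#' @param groups group label per accession.
#' @param ref_group,derived_group the two groups compared.
#' @param presence_frac gain/loss presence threshold.
#' @param q_threshold FDR cutoff for DE.
#' @return data.frame (gene, class, p, q).
#' @export
expression_evolution <- function(expr, groups, ref_group, derived_group,
                                 presence_frac = 0.9, q_threshold = 0.05) {
  sel <- groups %in% c(ref_group, derived_group)
  de <- group_de(expr[, sel, drop = FALSE], groups[sel],
                 q_threshold = q_threshold)
  gl <- classify_gain_loss(expr, groups, ref_group, derived_group,
                           presence_frac = presence_frac)
  expressed_both <- rowSums(expr[, groups == ref_group, drop = FALSE] > 0) > 0 &
    rowSums(expr[, groups == derived_group, drop = FALSE] > 0) > 0
  cls <- ifelse(gl != "none", gl,
                ifelse(de$de & expressed_both, "DE", "NS"))
  data.frame(gene = de$gene, class = cls, p = de$p, q = de$q,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Shannon-Wiener diversity of transcript abundance
#'
#' Entropy of the distribution of accessions over ten abundance intervals
#' scaled by the dispersion of the gene: with mean x and dispersion d
#' (sample standard deviation across accessions), the two open tails lie
#' beyond x +/- 2d and eight inner bins of width 0.5 d tile the middle.
#' H' = -sum p_i log2 p_i over the occupied bins, so H' ranges from 0 (all
#' accessions in one bin) to log2 10. The statistic is invariant to affine
#' rescaling of the abundances. d = 0 returns 0 by convention.
#'
#' @param values abundance of one gene across accessions (length >= 2).
#' @return H' in bits.
#' @export
shannon_h <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 accessions")
  m <- mean(values)
  d <- sd(values)
  if (d == 0) return(0)
  breaks <- m + c(-Inf, seq(-2, 2, by = 0.5), Inf) * d
  bin <- cut(values, breaks = breaks, right = FALSE, labels = FALSE)
  p <- tabulate(bin, nbins = 10) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Per-gene expression diversity, optionally by group
#'
#' @param expr genes x accessions abundance matrix.
#' @param groups optional group labels; when given, H' is also computed
#'   within each group.
#' @return data.frame with gene, h_all and one h_<group> column per group.
#' @export
expression_diversity <- function(expr, groups = NULL) {
  out <- data.frame(gene = rownames(expr),
                    h_all = apply(expr, 1, shannon_h),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(groups)) {
    for (g in unique(groups)) {
      out[[paste0("h_", g)]] <-
        apply(expr[, groups == g, drop = FALSE], 1, shannon_h)
    }
  }
  out
}

#' Gene-trait Pearson correlation
#'
#' Pearson r and its two-sided t-test P value for every gene x trait pair
#' over accessions present in both tables. Genes or traits with zero
#' variance are reported as missing.
#'
#' @param expr genes x accessions abundance matrix.
#' @param traits data.frame with an `accession` column and numeric trait
#'   columns.
#' @return long data.frame (gene, trait, r, p).
#' @export
trait_correlation <- function(expr, traits) {
  acc <- intersect(colnames(expr), traits$accession)
  if (length(acc) < 3) stop("need at least 3 paired accessions")
  e <- expr[, acc, drop = FALSE]
  t_num <- traits[match(acc, traits$accession),
                  setdiff(names(traits), "accession"), drop = FALSE]
  n <- length(acc)
  out <- list()
  for (tr in names(t_num)) {
    y <- t_num[[tr]]
    sdy <- sd(y)
    sde <- apply(e, 1, sd)
    r <- suppressWarnings(as.numeric(cor(t(e), y)))
    r[sde == 0 | sdy == 0] <- NA_real_
    tt <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tt), df = n - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
    out[[tr]] <- data.frame(gene = rownames(expr), trait = tr, r = r, p = p,
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of a gene set in trait-correlated genes
#'
#' Two-sided Fisher's exact test on the 2x2 table of membership in the
#' changed-gene set against membership in the trait-correlated set, over
#' the gene universe. Enrichment is significant below `alpha`.
#'
#' @param changed_genes gene ids whose expression changed.
#' @param correlated_genes gene ids significantly correlated with a trait.
#' @param universe all tested gene ids.
#' @param alpha significance level for the `significant` flag.
#' @return list with the 2x2 `table`, `p`, `odds_ratio`, `significant`.
#' @export
enrichment <- function(changed_genes, correlated_genes, universe,
                       alpha = 0.001) {
  if (!length(universe)) stop("empty gene universe")
  changed_genes <- intersect(changed_genes, universe)
  correlated_genes <- intersect(correlated_genes, universe)
  in_c <- universe %in% changed_genes
  in_r <- universe %in% correlated_genes
  tab <- matrix(c(sum(in_c & in_r), sum(!in_c & in_r),
                  sum(in_c & !in_r), sum(!in_c & !in_r)),
                nrow = 2,
                dimnames = list(changed = c("yes", "no"),
                                correlated = c("yes", "no")))
  ft <- fisher.test(tab)
  list(table = tab, p = ft$p.value,
       odds_ratio = unname(ft$estimate),
       significant = ft$p.value < alpha)
}
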