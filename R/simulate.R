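#' Specify a multi-population genotype simulation
#'
#' Defines a Balding-Nichols model for a set of diverged populations sampled
#' from a common ancestral gene pool. Each population i drifts from the
#' ancestral allele frequency p0 according to a divergence parameter F_i, so
#' that its frequency is Beta(p0(1-F_i)/F_i, (1-p0)(1-F_i)/F_i). For this
#' model the expected pairwise Hudson FST between populations i and j is
#' (F_i + F_j)/2, which lets `fst_targets` be honoured directly: the per-
#' population F are solved (least squares; exact for three populations) from
#' the requested pairwise matrix.
#'
#' The defaults emulate a clonal crop collection with an origin group and two
#' independently domesticated cultivated groups: 10 + 35 + 39 accessions and
#' pairwise divergence of roughly 0.35-0.47.
#'
#' @param sample_sizes named integer vector of accessions per population
#'   (each >= 2).
#' @param n_sites number of biallelic SNPs to simulate.
#' @param chrom_length chromosome length in bp; sites are placed uniformly.
#' @param fst_targets symmetric matrix of pairwise FST targets in [0,1) with
#'   zero diagonal, dimension length(sample_sizes).
#' @param ancestral_freq_beta shape parameters (alpha, beta) of the Beta
#'   distribution of ancestral frequencies, truncated to (0.05, 0.95) so
#'   every site is genuinely polymorphic in the ancestor.
#' @param clonal if TRUE, each population consists of `clone_lineages` clone
#'   lineages whose members share a genotype up to `clone_error`.
#' @param clone_lineages clone lineages per population (clonal mode).
#' @param clone_error per-genotype probability that a clone member's call
#'   deviates from its lineage (genotyping error); 0 gives exact identity.
#' @param seed RNG seed used by [simulate_genotypes()].
#'
#' @return An object of class `population_model`.
#' @export
population_model <- function(sample_sizes = c(OG = 10, CG1 = 35, CG2 = 39),
                             n_sites = 10000,
                             chrom_length = 2e7,
                             fst_targets = default_fst_targets(names(sample_sizes)),
                             ancestral_freq_beta = c(1, 1),
                             clonal = FALSE,
                             clone_lineages = 4,
                             clone_error = 0.01,
                             seed = 1L) {
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- paste0("pop", seq_along(sample_sizes))
  k <- length(sample_sizes)
  if (any(sample_sizes < 2)) stop("all sample_sizes must be >= 2")
  fst_targets <- as.matrix(fst_targets)
  if (!isTRUE(all.equal(fst_targets, t(fst_targets))) ||
      any(diag(fst_targets) != 0))
    stop("fst_targets must be symmetric with zero diagonal")
  if (any(fst_targets < 0) || any(fst_targets >= 1))
    stop("fst_targets must lie in [0, 1)")
  if (nrow(fst_targets) != k) stop("fst_targets dimension mismatch")
  stopifnot(length(ancestral_freq_beta) == 2, all(ancestral_freq_beta > 0),
            n_sites >= 1, chrom_length >= n_sites)
  structure(list(sample_sizes = sample_sizes, n_sites = as.integer(n_sites),
                 chrom_length = as.integer(chrom_length),
                 fst_targets = fst_targets,
                 ancestral_freq_beta = ancestral_freq_beta,
                 clonal = clonal, clone_lineages = as.integer(clone_lineages),
                 clone_error = clone_error, seed = as.integer(seed)),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("population_model:", length(x$sample_sizes), "populations,",
      x$n_sites, "sites over", x$chrom_length, "bp\n")
  print(x$sample_sizes)
  invisible(x)
}

#' Default pairwise divergence targets for the three-group design
#'
#' Origin group vs the two cultivated groups at 0.35 and 0.47, and 0.40
#' between the cultivated groups, matching genome-wide divergence levels
#' typical of strongly structured clonal crops.
#' @param pops population names (length 3 for the default design).
#' @return symmetric FST target matrix.
#' @export
default_fst_targets <- function(pops = c("OG", "CG1", "CG2")) {
  k <- length(pops)
  m <- matrix(0.4, k, k, dimnames = list(pops, pops))
  diag(m) <- 0
  if (k == 3) {
    m[1, 2] <- m[2, 1] <- 0.35
    m[1, 3] <- m[3, 1] <- 0.47
    m[2, 3] <- m[3, 2] <- 0.40
  }
  m
}

# Solve per-population Balding-Nichols divergence F_i from pairwise targets
# using E[FST_ij] = (F_i + F_j)/2 (exact solution for 3 pops, least squares
# otherwise). Clamped to [0, 0.999].
solve_bn_divergence <- function(fst_targets) {
  k <- nrow(fst_targets)
  if (k == 1) return(0)
  pairs <- which(upper.tri(fst_targets), arr.ind = TRUE)
  A <- matrix(0, nrow(pairs), k)
  A[cbind(seq_len(nrow(pairs)), pairs[, 1])] <- 0.5
  A[cbind(seq_len(nrow(pairs)), pairs[, 2])] <- 0.5
  b <- fst_targets[pairs]
  f <- if (nrow(pairs) == k) solve(crossprod(A), crossprod(A, b))
       else qr.solve(A, b)
  pmin(pmax(as.numeric(f), 0), 0.999)
}

#' Simulate diploid genotypes under the Balding-Nichols model
#'
#' Draws ancestral frequencies, per-population drifted frequencies, and
#' binomial diploid genotypes for every accession. Per-genotype depth (DP)
#' and genotype quality (GQ) and per-site QUAL values are generated so the
#' quality-control filters are exercisable on simulated data. In clonal mode
#' accessions within a population are copies of a small number of clone
#' lineages, perturbed at rate `clone_error`.
#'
#' @param model a [population_model()].
#' @return A [geno_matrix()] with population labels, ref (ancestral) and alt
#'   (derived) alleles, DP/GQ/QUAL annotations and the chromosome length in
#'   `$chrom_len`.
#' @export
simulate_genotypes <- function(model) {
  stopifnot(inherits(model, "population_model"))
  set.seed(model$seed)
  k <- length(model$sample_sizes)
  n_sites <- model$n_sites
  pos <- sort(sample.int(model$chrom_length, n_sites))
  ab <- model$ancestral_freq_beta
  # ancestral frequencies from a Beta truncated to (0.05, 0.95)
  lo <- pbeta(0.05, ab[1], ab[2]); hi <- pbeta(0.95, ab[1], ab[2])
  p0 <- qbeta(runif(n_sites, lo, hi), ab[1], ab[2])
  f <- solve_bn_divergence(model$fst_targets)
  pop_names <- names(model$sample_sizes)
  freqs <- matrix(NA_real_, n_sites, k)
  for (i in seq_len(k)) {
    freqs[, i] <- if (f[i] <= 0) p0 else {
      lam <- (1 - f[i]) / f[i]
      rbeta(n_sites, p0 * lam, (1 - p0) * lam)
    }
  }
  n_total <- sum(model$sample_sizes)
  geno <- matrix(NA_integer_, n_sites, n_total)
  pops <- rep(pop_names, model$sample_sizes)
  col0 <- 0L
  for (i in seq_len(k)) {
    ni <- model$sample_sizes[i]
    cols <- col0 + seq_len(ni)
    if (model$clonal) {
      nl <- min(model$clone_lineages, ni)
      lineage_geno <- matrix(rbinom(n_sites * nl, 2, rep(freqs[, i], nl)),
                             n_sites, nl)
      assign <- rep_len(seq_len(nl), ni)
      g <- lineage_geno[, assign, drop = FALSE]
      if (model$clone_error > 0) {
        err <- matrix(runif(n_sites * ni) < model$clone_error, n_sites, ni)
        g[err] <- rbinom(sum(err), 2, rep(freqs[, i], ni)[err])
      }
      geno[, cols] <- g
    } else {
      geno[, cols] <- matrix(rbinom(n_sites * ni, 2, rep(freqs[, i], ni)),
                             n_sites, ni)
    }
    col0 <- col0 + ni
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  dp <- matrix(rpois(n_sites * n_total, 9), n_sites, n_total)
  gq <- matrix(pmin(99L, rpois(n_sites * n_total, 40)), n_sites, n_total)
  qual <- round(rlnorm(n_sites, meanlog = log(300), sdlog = 1), 2)
  samples <- paste0(rep(pop_names, model$sample_sizes), "_",
                    unlist(lapply(model$sample_sizes, seq_len)))
  gm <- geno_matrix(geno, chrom = rep("chr1", n_sites), pos = pos,
                    ref = ref, alt = unname(alt), samples = samples,
                    pops = pops, qual = qual, dp = dp, gq = gq)
  gm$chrom_len <- c(chr1 = model$chrom_length)
  gm
}

#' Specify a selective sweep to inject
#'
#' @param target_pop population label subjected to selection.
#' @param start,end sweep interval in bp, 0-based half-open.
#' @param diversity_reduction fraction in (0, 1] of target-population
#'   genotypes in the region replaced by the regional major-allele
#'   homozygote; 1 collapses the region to fixation.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(target_pop, start, end, diversity_reduction = 0.9) {
  if (end <= start) stop("empty sweep region")
  if (!(diversity_reduction > 0 && diversity_reduction <= 1))
    stop("diversity_reduction must lie in (0, 1]")
  structure(list(target_pop = target_pop, start = start, end = end,
                 diversity_reduction = diversity_reduction),
            class = "sweep_spec")
}

#' Inject a selective sweep into simulated genotypes
#'
#' Within the sweep interval, each target-population genotype is replaced by
#' the homozygote of the site's major allele (in the target population) with
#' probability `diversity_reduction`, collapsing local diversity towards
#' fixation while leaving other populations and out-of-region sites intact.
#'
#' @param gm a [geno_matrix()].
#' @param spec a [sweep_spec()].
#' @param seed optional seed for the replacement draws.
#' @return The modified `geno_matrix`.
#' @export
inject_sweep <- function(gm, spec, seed = NULL) {
  stopifnot(inherits(spec, "sweep_spec"))
  if (!is.null(seed)) set.seed(seed)
  in_region <- gm$pos > spec$start & gm$pos <= spec$end
  if (!any(in_region)) stop("sweep region contains no simulated sites")
  cols <- pop_cols(gm, spec$target_pop)
  g <- gm$geno[in_region, cols, drop = FALSE]
  p <- rowMeans(g, na.rm = TRUE) / 2
  major_hom <- ifelse(p >= 0.5, 2L, 0L)
  hit <- matrix(runif(length(g)) < spec$diversity_reduction,
                nrow(g), ncol(g))
  g[hit] <- rep(major_hom, ncol(g))[hit]
  gm$geno[in_region, cols] <- g
  gm
}

#' Assign simulated deleterious scores to sites
#'
#' Produces a per-site functional-impact score on the SIFT scale (0 = most
#' damaging): a chosen fraction of sites get a score <= 0.05 (deleterious),
#' the rest > 0.05 (tolerated). With `freq_bias > 0` deleterious status is
#' biased towards sites with low derived-allele frequency, emulating
#' purifying selection keeping damaging alleles rare.
#'
#' @param gm a [geno_matrix()].
#' @param fraction fraction of sites flagged deleterious, in (0, 1); the
#'   flagged count is round(fraction * n_sites) exactly.
#' @param freq_bias exponent of the (1 - derived frequency) sampling weight;
#'   0 gives frequency-independent assignment.
#' @param seed RNG seed.
#' @return data.frame with chrom, pos, score and logical `deleterious`.
#' @export
assign_deleterious <- function(gm, fraction = 0.2864, freq_bias = 0,
                               seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  n <- length(gm$pos)
  n_del <- round(fraction * n)
  p <- site_allele_stats(gm, seq_along(gm$samples))$p
  w <- if (freq_bias > 0) (1 - p)^freq_bias else rep(1, n)
  w[is.na(w) | w <= 0] <- min(w[w > 0], na.rm = TRUE) * 1e-6
  del_idx <- sample.int(n, n_del, prob = w)
  score <- runif(n, 0.0500001, 1)
  score[del_idx] <- runif(n_del, 0, 0.05)
  data.frame(chrom = gm$chrom, pos = gm$pos, score = score,
             deleterious = seq_len(n) %in% del_idx)
}

#' Specify an expression-evolution simulation
#'
#' @param n_genes number of genes.
#' @param groups group names (default origin + two cultivated groups).
#' @param group_shift optional n_genes x n_groups matrix of log2-scale mean
#'   shifts (default zero: no group effect).
#' @param gained_genes named list (group -> gene indices) of genes expressed
#'   only in that group (zero elsewhere).
#' @param lost_genes named list (group -> gene indices) of genes with zero
#'   expression in that group but expressed elsewhere.
#' @param trait_drivers data.frame(gene, trait, weight): genes whose
#'   abundance linearly drives a trait.
#' @param noise_sd residual SD on the log2 scale (> 0).
#' @param trait_noise_sd trait noise SD expressed relative to the SD of the
#'   genetic trait signal (1 = noise as large as signal).
#' @param seed RNG seed.
#' @return An object of class `expression_model`.
#' @export
expression_model <- function(n_genes = 1000,
                             groups = c("OG", "CG1", "CG2"),
                             group_shift = NULL,
                             gained_genes = list(),
                             lost_genes = list(),
                             trait_drivers = NULL,
                             noise_sd = 0.8,
                             trait_noise_sd = 1,
                             seed = 1L) {
  stopifnot(n_genes >= 1, noise_sd > 0)
  if (is.null(group_shift))
    group_shift <- matrix(0, n_genes, length(groups),
                          dimnames = list(NULL, groups))
  stopifnot(nrow(group_shift) == n_genes,
            ncol(group_shift) == length(groups))
  special <- c(unlist(gained_genes), unlist(lost_genes),
               if (!is.null(trait_drivers)) trait_drivers$gene)
  gl <- c(unlist(gained_genes), unlist(lost_genes))
  if (anyDuplicated(gl))
    stop("gained_genes and lost_genes assignments overlap")
  if (!is.null(trait_drivers) &&
      any(trait_drivers$gene %in% gl))
    stop("trait driver genes must be disjoint from gained/lost genes")
  if (length(special) && (min(special) < 1 || max(special) > n_genes))
    stop("gene indices out of range")
  bad_groups <- setdiff(c(names(gained_genes), names(lost_genes)), groups)
  if (length(bad_groups)) stop("unknown group: ", paste(bad_groups, collapse = ","))
  structure(list(n_genes = as.integer(n_genes), groups = groups,
                 group_shift = group_shift, gained_genes = gained_genes,
                 lost_genes = lost_genes, trait_drivers = trait_drivers,
                 noise_sd = noise_sd, trait_noise_sd = trait_noise_sd,
                 seed = as.integer(seed)),
            class = "expression_model")
}

#' Simulate an expression matrix and linearly driven traits
#'
#' Gene abundances are lognormal on the FPKM scale: per-gene baseline log2
#' mean ~ N(3, 1.5), plus the model's group shift and N(0, noise_sd) residual
#' noise. Genes listed as gained for a group are zeroed everywhere else;
#' genes lost in a group are zeroed there. Traits are a linear combination of
#' driver-gene abundances plus Gaussian noise scaled to the signal SD; traits
#' without drivers are pure noise around a baseline.
#'
#' @param em an [expression_model()].
#' @param groups named character vector: accession id -> group label, which
#'   must cover all of `em$groups`.
#' @param traits trait names to simulate.
#' @return list with `expr` (genes x accessions FPKM matrix), `traits`
#'   (data.frame accession + one column per trait) and `groups`.
#' @export
simulate_expression <- function(em, groups,
                                traits = c("clove_number", "clove_weight",
                                           "bulb_weight", "bulb_diameter")) {
  stopifnot(inherits(em, "expression_model"))
  if (is.null(names(groups)))
    names(groups) <- paste0("A", seq_along(groups))
  if (!all(em$groups %in% groups))
    stop("group labels must cover all model groups")
  set.seed(em$seed)
  n_acc <- length(groups)
  base <- rnorm(em$n_genes, 3, 1.5)
  shift <- em$group_shift[, match(groups, colnames(em$group_shift)),
                          drop = FALSE]
  logx <- base + shift +
    matrix(rnorm(em$n_genes * n_acc, 0, em$noise_sd), em$n_genes, n_acc)
  expr <- 2^logx
  for (grp in names(em$gained_genes))
    expr[em$gained_genes[[grp]], groups != grp] <- 0
  for (grp in names(em$lost_genes))
    expr[em$lost_genes[[grp]], groups == grp] <- 0
  rownames(expr) <- paste0("gene", seq_len(em$n_genes))
  colnames(expr) <- names(groups)
  trait_df <- data.frame(accession = names(groups))
  for (tr in traits) {
    drv <- em$trait_drivers[em$trait_drivers$trait == tr, , drop = FALSE]
    if (!is.null(drv) && nrow(drv)) {
      signal <- as.numeric(crossprod(expr[drv$gene, , drop = FALSE], drv$weight))
      s_sd <- sd(signal)
      if (!is.finite(s_sd) || s_sd == 0) s_sd <- 1
      trait_df[[tr]] <- signal + rnorm(n_acc, 0, em$trait_noise_sd * s_sd)
    } else {
      trait_df[[tr]] <- rnorm(n_acc, 10, 1)
    }
  }
  list(expr = expr, traits = trait_df, groups = groups)
}

#' Simulate non-overlapping gene models
#'
#' Places genes of 2-10 kb uniformly along the chromosome with at least
#' `min_gap` bp between them.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param chrom chromosome name.
#' @param min_gap minimum intergenic gap in bp.
#' @param seed RNG seed.
#' @return gene-model data.frame (gene_id, chrom, start, end, strand; 1-based
#'   inclusive coordinates as in GFF3), sorted by position.
#' @export
simulate_gene_models <- function(chrom_length, n_genes = 50, chrom = "chr1",
                                 min_gap = 1000, seed = 1L) {
  set.seed(seed)
  len <- round(runif(n_genes, 2000, 10000))
  if (sum(len) + (n_genes + 1) * min_gap > chrom_length)
    stop("chromosome too short for the requested genes")
  slack <- chrom_length - sum(len) - (n_genes + 1) * min_gap
  gaps <- min_gap + round(slack * diff(c(0, sort(runif(n_genes)))))
  start <- cumsum(gaps) + cumsum(c(0, len[-n_genes])) + 1
  data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
             chrom = chrom, start = as.integer(start),
             end = as.integer(start + len - 1),
             strand = sample(c("+", "-"), n_genes, replace = TRUE))
}

#' Write a complete simulated fixture bundle to disk
#'
#' Writes a VCF v4.2 (GT:DP:GQ), a GFF3 of gene features, and TSVs for
#' population assignments, per-site deleterious scores, expression, traits
#' and optionally externally computed XP-CLR window scores. The files
#' round-trip through the package readers with identical genotype content.
#'
#' @param gm a [geno_matrix()].
#' @param dir output directory (created if needed).
#' @param gene_model optional gene-model data.frame (see
#'   [simulate_gene_models()]).
#' @param scores optional deleterious score table ([assign_deleterious()]).
#' @param expression optional result of [simulate_expression()].
#' @param xpclr optional XP-CLR window table (chrom, start, end, score).
#' @return invisibly, the named vector of file paths written.
#' @export
write_fixture_bundle <- function(gm, dir, gene_model = NULL, scores = NULL,
                                 expression = NULL, xpclr = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             populations = file.path(dir, "populations.tsv"))
  write_vcf(gm, paths["vcf"])
  write.table(data.frame(accession = gm$samples, group = gm$pops),
              paths["populations"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(gene_model)) {
    paths["gff3"] <- file.path(dir, "genes.gff3")
    write_gff3(gene_model, paths["gff3"])
  }
  if (!is.null(scores)) {
    paths["scores"] <- file.path(dir, "sift_scores.tsv")
    write.table(scores[, c("chrom", "pos", "score")], paths["scores"],
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(expression)) {
    paths["expression"] <- file.path(dir, "expression.tsv")
    expr_df <- data.frame(gene = rownames(expression$expr),
                          expression$expr, check.names = FALSE)
    write.table(expr_df, paths["expression"], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths["traits"] <- file.path(dir, "traits.tsv")
    write.table(expression$traits, paths["traits"], sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(xpclr)) {
    paths["xpclr"] <- file.path(dir, "xpclr.tsv")
    write.table(xpclr, paths["xpclr"], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(paths)
}
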