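# hand-buildable genotype fixtures and brute-force oracles used across tests

# small genotype matrix from an explicit sites x accessions matrix
tiny_gm <- function(geno, pos = NULL, pops = NULL, chrom_len = NULL, ...) {
  geno <- as.matrix(geno)
  if (is.null(pos)) pos <- seq_len(nrow(geno)) * 10L
  gm <- geno_matrix(geno, chrom = rep("chr1", nrow(geno)), pos = pos,
                    pops = pops, ...)
  if (!is.null(chrom_len)) gm$chrom_len <- c(chr1 = chrom_len)
  gm
}

# random genotype matrix with DP/GQ/QUAL for QC tests
random_gm <- function(n_sites = 50, n_samp = 8, seed = 1, miss = 0.1) {
  set.seed(seed)
  geno <- matrix(sample(c(0:2, NA), n_sites * n_samp, replace = TRUE,
                        prob = c(0.5, 0.25, 0.15, miss)),
                 n_sites, n_samp)
  dp <- matrix(rpois(n_sites * n_samp, 6), n_sites, n_samp)
  gq <- matrix(sample(0:60, n_sites * n_samp, replace = TRUE),
               n_sites, n_samp)
  qual <- round(runif(n_sites, 5, 100), 1)
  pops <- rep(c("A", "B"), length.out = n_samp)
  gm <- tiny_gm(geno, pos = sort(sample.int(5000, n_sites)), pops = pops,
                dp = dp, gq = gq, qual = qual)
  gm$chrom_len <- c(chr1 = 5000L)
  gm
}

# independent per-variant positional classifier: scans every gene linearly,
# applying the precedence rules directly
brute_annotate <- function(pos, genes, flank = 1000) {
  vapply(pos, function(p) {
    in_gene <- any(p >= genes$start & p <= genes$end)
    if (in_gene) return("exonic")
    up <- any(ifelse(genes$strand == "-",
                     p > genes$end & p <= genes$end + flank,
                     p < genes$start & p >= genes$start - flank))
    if (up) return("upstream1kb")
    dn <- any(ifelse(genes$strand == "-",
                     p < genes$start & p >= genes$start - flank,
                     p > genes$end & p <= genes$end + flank))
    if (dn) return("downstream1kb")
    "intergenic"
  }, "")
}

# brute-force hypergeometric tail sum for a 2x2 Fisher test (two-sided by
# summing all tables with probability <= the observed one)
brute_fisher2x2 <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) dhyper(x, m, n, k), numeric(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

expect_windows_aligned <- function(a, b) {
  expect_equal(a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])
}
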