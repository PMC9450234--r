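test_that("PBS closed forms", {
  expect_equal(pbs(0, 0, 0), 0)
  t5 <- -log(1 - 0.5)
  expect_equal(pbs(0.5, 0.5, 0.5), t5 / 2, tolerance = 1e-9)
  expect_equal(pbs(0.5, 0.5, 0.5), 0.3465736, tolerance = 1e-6)
  expect_equal(pbs(0.5, 0.5, 0.9),
               (t5 + t5 + log(1 - 0.9)) / 2, tolerance = 1e-9)
  expect_equal(pbs(0.5, 0.5, 0.9), -0.4581454, tolerance = 1e-6)
  expect_warning(p1 <- pbs(1, 0.5, 0.5), "clamped")
  expect_true(is.finite(p1))
  expect_equal(pbs(-0.2, 0, 0), 0)
})

test_that("the three PBS values sum to (T_AB + T_AC + T_BC) / 2", {
  set.seed(4)
  for (i in 1:20) {
    f <- runif(3, 0, 0.9)  # AB, AC, BC
    total <- pbs(f[1], f[2], f[3]) + pbs(f[1], f[3], f[2]) +
      pbs(f[2], f[3], f[1])
    expect_equal(total, sum(-log(1 - f)) / 2, tolerance = 1e-12)
  }
})

test_that("PBS scan flags match a brute-force Z computation", {
  set.seed(6)
  n <- 60
  wt <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                   end = (1:n) * 1e5,
                   fst_tp_cp = runif(n, 0, 0.6), fst_tp_co = runif(n, 0, 0.6),
                   fst_cp_co = runif(n, 0, 0.6))
  out <- pbs_scan(wt)
  p <- (-log(1 - wt$fst_tp_cp) - log(1 - wt$fst_tp_co) +
          log(1 - wt$fst_cp_co)) / 2
  z <- (p - mean(p)) / sd(p)
  expect_equal(out$pbs, p)
  expect_identical(out$selected, z > qnorm(0.95))

  same <- wt
  same[, 4:6] <- 0.3
  expect_warning(res <- pbs_scan(same), "zero variance")
  expect_false(any(res$selected))
  expect_error(pbs_scan(wt[1:10, ]), "at least 30")
})

test_that("pi-ratio scan computes log2 ratios and tail flags", {
  n <- 40
  grid <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5,
                     end = (1:n) * 1e5)
  set.seed(8)
  piA <- cbind(grid, pi = runif(n, 1e-4, 1e-3))
  piB <- cbind(grid, pi = piA$pi)
  piA$pi[5] <- 0.001; piB$pi[5] <- 0.004
  out <- pi_ratio_scan(piA, piB)
  expect_equal(out$log2_ratio[5], -2)

  # a zero-diversity window is excluded from the quantiles and never flagged
  piA$pi[6] <- 0
  out2 <- pi_ratio_scan(piA, piB)
  expect_true(is.na(out2$log2_ratio[6]))
  expect_false(out2$selected_A[6] || out2$selected_B[6])

  misaligned <- piB; misaligned$start <- misaligned$start + 1
  expect_error(pi_ratio_scan(piA, misaligned), "aligned")
})

test_that("pi-ratio outlier tails recover an injected sweep", {
  gm <- simulate_genotypes(population_model(n_sites = 8000, seed = 33))
  swept <- inject_sweep(gm, sweep_spec("CG1", 8e6, 11e6, 0.95), seed = 1)
  piOG <- window_pi(swept, "OG")
  piCG1 <- window_pi(swept, "CG1")
  # log2(pi_OG / pi_CG1): selection in CG1 appears in the upper tail
  out <- pi_ratio_scan(piOG, piCG1)
  sweep_windows <- out$start >= 8e6 & out$end <= 11e6
  expect_gt(sum(out$selected_B[sweep_windows], na.rm = TRUE), 0)
  expect_gt(mean(out$log2_ratio[sweep_windows], na.rm = TRUE),
            mean(out$log2_ratio[!sweep_windows], na.rm = TRUE))
})

test_that("XP-CLR ingestion flags the top scores with inclusive ties", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_identical(nrow(load_xpclr(empty)), 0L)

  ties <- data.frame(chrom = "chr1", start = (0:99) * 1e5, end = (1:100) * 1e5,
                     score = 1)
  expect_true(all(load_xpclr(ties)$selected))

  set.seed(10)
  rnd <- data.frame(chrom = "chr1", start = (0:999) * 1e5,
                    end = (1:1000) * 1e5, score = rnorm(1000))
  out <- load_xpclr(rnd)
  thr <- sort(rnd$score, decreasing = TRUE)[ceiling(0.05 * 1000)]
  expect_identical(out$selected, rnd$score >= thr)
  expect_identical(sum(out$selected), 50L)

  bad <- rnd; bad$score <- as.character(bad$score); bad$score[3] <- "x"
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_xpclr(path), "malformed")
})

test_that("consensus calling requires two supporting methods", {
  w <- function(s, e, sel = TRUE)
    data.frame(chrom = "chr1", start = s, end = e, selected = sel)
  one <- consensus_sweeps(list(pbs = w(0, 5e5), piratio = w(9e5, 9.5e5)),
                          min_support = 2)
  expect_identical(nrow(one), 0L)

  two <- consensus_sweeps(list(pbs = w(0, 5e5), piratio = w(2e5, 7e5)))
  expect_equal(two$start, 2e5)
  expect_equal(two$end, 5e5)
  expect_identical(two$n_methods, 2L)

  three <- consensus_sweeps(list(a = w(1e5, 2e5), b = w(1e5, 2e5),
                                 c = w(1e5, 2e5)))
  expect_identical(nrow(three), 1L)
  expect_identical(three$supporters, "a,b,c")
  expect_identical(three$n_methods, 3L)
})

test_that("consensus regions are monotone in min_support and within the union", {
  set.seed(12)
  mk <- function(seed) {
    set.seed(seed)
    n <- 50
    data.frame(chrom = "chr1", start = (0:(n - 1)) * 1e5, end = (1:n) * 1e5,
               selected = runif(n) < 0.3)
  }
  methods <- list(a = mk(1), b = mk(2), c = mk(3))
  bp <- function(sw) sum(sw$end - sw$start)
  s2 <- consensus_sweeps(methods, min_support = 2)
  s3 <- consensus_sweeps(methods, min_support = 3)
  expect_lte(bp(s3), bp(s2))
  union_bp <- sum(Reduce(`|`, lapply(methods, function(m) m$selected)))
  expect_lte(bp(s2) / 1e5, union_bp)
  # every bp of a min_support=3 region is inside some min_support=2 region
  if (nrow(s3)) {
    for (i in seq_len(nrow(s3))) {
      expect_true(any(s2$start <= s3$start[i] & s2$end >= s3$end[i]))
    }
  }
})

test_that("gene assignment respects half-open region bounds", {
  genes <- data.frame(gene_id = c("in", "abut", "span"), chrom = "chr1",
                      start = c(1100L, 2001L, 1900L),
                      end = c(1500L, 2500L, 2100L))
  sweeps <- data.frame(chrom = "chr1", start = 1000L, end = 2000L)
  out <- assign_genes(sweeps, genes)
  # region covers bases 1001..2000 (1-based): "abut" starts at 2001 -> out
  expect_setequal(out$genes[[1]], c("in", "span"))

  # random fixture vs brute force
  set.seed(14)
  g2 <- simulate_gene_models(1e6, n_genes = 30, seed = 3)
  sw2 <- data.frame(chrom = "chr1", start = sort(sample.int(9e5, 5)) ,
                    end = NA)
  sw2$end <- sw2$start + 5e4
  out2 <- assign_genes(sw2, g2)
  for (i in seq_len(nrow(sw2))) {
    brute <- g2$gene_id[g2$end >= sw2$start[i] + 1 & g2$start <= sw2$end[i]]
    expect_setequal(out2$genes[[i]], brute)
  }
})

test_that("shared sweeps intersect intervals and gene sets", {
  a <- data.frame(chrom = "chr1", start = c(0, 5e5), end = c(2e5, 8e5))
  a$genes <- list(c("g1", "g2"), "g3")
  b <- data.frame(chrom = "chr1", start = 1e5, end = 6e5)
  b$genes <- list(c("g2", "g4"))
  sh <- shared_sweeps(a, b)
  expect_equal(sh$regions$start, c(1e5, 5e5))
  expect_equal(sh$regions$end, c(2e5, 6e5))
  expect_identical(sh$shared_genes, "g2")

  disjoint <- shared_sweeps(
    data.frame(chrom = "chr1", start = 0, end = 1e5),
    data.frame(chrom = "chr1", start = 2e5, end = 3e5))
  expect_identical(nrow(disjoint$regions), 0L)

  same <- shared_sweeps(a, a)
  expect_equal(same$regions$start, a$start)
  expect_setequal(same$shared_genes, c("g1", "g2", "g3"))
})

test_that("Patterson's D matches site-pattern arithmetic", {
  # haploid-like toy: populations fixed at each site, 30 ABBA + 10 BABA
  n_ab <- 30; n_ba <- 10
  geno <- rbind(
    matrix(rep(c(0L, 0L, 2L, 2L, 2L, 2L, 0L, 0L), n_ab), n_ab, 8, byrow = TRUE),
    matrix(rep(c(2L, 2L, 0L, 0L, 2L, 2L, 0L, 0L), n_ba), n_ba, 8, byrow = TRUE))
  gm <- tiny_gm(geno, pops = rep(c("P1", "P2", "P3", "OUT"), each = 2),
                pos = seq_len(n_ab + n_ba) * 1000L)
  d <- patterson_d(gm, "P1", "P2", "P3", "OUT", block_bp = 5000)
  expect_equal(d$D, 0.5)
  expect_equal(d$abba, 30)
  expect_equal(d$baba, 10)

  # swapping P1 and P2 flips the sign
  d_swap <- patterson_d(gm, "P2", "P1", "P3", "OUT", block_bp = 5000)
  expect_equal(d_swap$D, -0.5)

  # balanced patterns give D = 0
  bal <- rbind(geno[1:10, ], geno[31:40, ])
  gm_bal <- tiny_gm(bal, pops = rep(c("P1", "P2", "P3", "OUT"), each = 2),
                    pos = seq_len(20) * 1000L)
  expect_equal(patterson_d(gm_bal, "P1", "P2", "P3", "OUT",
                           block_bp = 3000)$D, 0)

  no_info <- tiny_gm(matrix(0L, 3, 8),
                     pops = rep(c("P1", "P2", "P3", "OUT"), each = 2))
  expect_error(patterson_d(no_info, "P1", "P2", "P3", "OUT"), "informative")
})

test_that("null simulations give calibrated D Z-scores", {
  hits <- 0L
  n_seeds <- 20
  pops <- c("P1", "P2", "P3", "OUT")
  tg <- matrix(0.3, 4, 4, dimnames = list(pops, pops)); diag(tg) <- 0
  for (seed in seq_len(n_seeds)) {
    gm <- simulate_genotypes(population_model(
      sample_sizes = c(P1 = 8, P2 = 8, P3 = 8, OUT = 6), n_sites = 4000,
      chrom_length = 2e7, fst_targets = tg, seed = 100 + seed))
    d <- patterson_d(gm, "P1", "P2", "P3", "OUT", block_bp = 1e6)
    if (abs(d$Z) < 3) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})
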