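test_that("FPKM arithmetic", {
  expect_equal(fpkm(100, 1000, 1e6), 100)
  expect_equal(fpkm(0, 1000, 1e6), 0)
  expect_equal(fpkm(100, 1000, 2e6), 50)
  expect_error(fpkm(10, 0, 1e6), "length")
  expect_error(fpkm(10, 1000, 0), "library")
})

test_that("group ANOVA matches stats::anova and controls the FDR", {
  set.seed(25)
  groups <- rep(c("OG", "CG1", "CG2"), each = 9)
  expr <- matrix(rlnorm(20 * 27), 20, 27,
                 dimnames = list(paste0("g", 1:20), NULL))
  out <- group_de(expr, groups)
  # cross-check a handful of genes against the base fitter
  for (i in c(1, 7, 20)) {
    fit <- anova(lm(expr[i, ] ~ factor(groups)))
    expect_equal(out$p[i], fit$`Pr(>F)`[1], tolerance = 1e-10)
  }
  expect_equal(out$q, p.adjust(out$p, "BH"))

  # null: the q < 0.05 discovery fraction stays within FDR bounds
  set.seed(26)
  null_expr <- matrix(rlnorm(1000 * 27), 1000, 27,
                      dimnames = list(paste0("g", 1:1000), NULL))
  null_out <- group_de(null_expr, groups)
  expect_lte(mean(null_out$de), 0.05)

  # strong shift is detected; constant gene is NS with P = 1
  shifted <- null_expr
  shifted[1, groups == "CG1"] <- shifted[1, groups == "CG1"] + 50
  shifted[2, ] <- 7
  out2 <- group_de(shifted, groups)
  expect_true(out2$de[1])
  expect_equal(out2$p[2], 1)
  expect_false(out2$de[2])
  expect_error(group_de(expr, rep("A", 27)), "2 groups")
  expect_error(group_de(expr[, 1:4], c("A", "A", "B", "B")), "3 accessions")
})

test_that("BH q-values are monotone and nested across thresholds", {
  set.seed(27)
  groups <- rep(c("A", "B"), each = 10)
  expr <- matrix(rlnorm(200 * 20), 200, 20,
                 dimnames = list(paste0("g", 1:200), NULL))
  expr[1:20, groups == "B"] <- expr[1:20, groups == "B"] * 8
  out <- group_de(expr, groups)
  ord <- order(out$p)
  expect_true(all(diff(out$q[ord]) >= -1e-12))
  de05 <- out$gene[out$q < 0.05]
  de10 <- out$gene[out$q < 0.10]
  expect_true(all(de05 %in% de10))
})

test_that("gain/loss classification follows the 90% presence rules", {
  groups <- rep(c("OG", "CG1", "CG2"), times = c(10, 20, 20))
  expr <- matrix(1, 5, 50, dimnames = list(paste0("g", 1:5), NULL))
  expr[1, ] <- 0                                   # silent everywhere
  expr[2, groups == "OG"] <- 0                     # EE in both CGs
  expr[3, ] <- 1; expr[3, groups == "CG2"] <- 0    # LE in CG2
  # zero in all OG but only 85% of CG1 expressing -> not EE for CG1
  expr[4, groups == "OG"] <- 0
  expr[4, which(groups == "CG1")[1:3]] <- 0
  out_cg1 <- classify_gain_loss(expr, groups, "OG", "CG1")
  out_cg2 <- classify_gain_loss(expr, groups, "OG", "CG2")
  expect_identical(unname(out_cg1[1:4]), c("none", "EE", "none", "none"))
  expect_identical(unname(out_cg2[1:4]), c("none", "EE", "LE", "EE"))
  expect_error(classify_gain_loss(expr, groups, "XX", "CG1"), "empty")

  # invariant to accession order
  perm <- sample(50)
  expect_identical(classify_gain_loss(expr[, perm], groups[perm], "OG", "CG1"),
                   out_cg1)
})

test_that("simulated gained/lost genes are recovered exactly", {
  groups <- setNames(rep(c("OG", "CG1", "CG2"), times = c(9, 36, 36)),
                     paste0("A", 1:81))
  em <- expression_model(n_genes = 60, seed = 6,
                         gained_genes = list(CG1 = 1:4),
                         lost_genes = list(CG2 = 5:8))
  sim <- simulate_expression(em, groups)
  gl <- classify_gain_loss(sim$expr, sim$groups, "OG", "CG1")
  expect_identical(which(gl == "EE"), setNames(1:4, paste0("gene", 1:4)))
  gl2 <- classify_gain_loss(sim$expr, sim$groups, "OG", "CG2")
  expect_identical(which(gl2 == "LE"), setNames(5:8, paste0("gene", 5:8)))
})

test_that("the evolution classes are exclusive and exhaustive", {
  groups <- setNames(rep(c("OG", "CG1", "CG2"), times = c(9, 36, 36)),
                     paste0("A", 1:81))
  shift <- matrix(0, 80, 3, dimnames = list(NULL, c("OG", "CG1", "CG2")))
  shift[10:20, "CG1"] <- 4
  em <- expression_model(n_genes = 80, seed = 7, group_shift = shift,
                         gained_genes = list(CG1 = 1:3),
                         lost_genes = list(CG1 = 4:6))
  sim <- simulate_expression(em, groups)
  ev <- expression_evolution(sim$expr, sim$groups, "OG", "CG1")
  expect_identical(nrow(ev), 80L)
  expect_true(all(ev$class %in% c("EE", "LE", "DE", "NS")))
  expect_identical(sum(table(ev$class)), 80L)
  expect_identical(ev$class[1:6], c(rep("EE", 3), rep("LE", 3)))
  expect_true(all(ev$class[10:20] == "DE"))
})

test_that("Shannon-Wiener H' behaves as an entropy over dispersion bins", {
  expect_equal(shannon_h(rep(3.7, 10)), 0)
  expect_error(shannon_h(5), "at least 2")

  set.seed(28)
  x <- rnorm(81)
  h <- shannon_h(x)
  expect_gt(h, 0); expect_lte(h, log2(10))
  # affine invariance: bins scale with the mean and dispersion
  expect_equal(shannon_h(5 + 3 * x), h)
  expect_equal(shannon_h(-2 * x + 1), h)

  # n = 81 normal draws concentrate near the closed-form normal-bin entropy
  probs <- diff(pnorm(c(-Inf, seq(-2, 2, 0.5), Inf)))
  h_exact <- -sum(probs * log2(probs))
  expect_equal(h_exact, 3.012019, tolerance = 1e-6)
  hs <- vapply(1:60, function(s) { set.seed(400 + s); shannon_h(rnorm(81)) },
               numeric(1))
  expect_lt(abs(mean(hs) - h_exact), 0.15)
})

test_that("per-gene diversity table covers groups and all accessions", {
  set.seed(29)
  groups <- rep(c("OG", "CG1"), each = 10)
  expr <- matrix(rlnorm(5 * 20), 5, 20,
                 dimnames = list(paste0("g", 1:5), NULL))
  dv <- expression_diversity(expr, groups)
  expect_identical(names(dv), c("gene", "h_all", "h_OG", "h_CG1"))
  expect_true(all(dv$h_all >= 0 & dv$h_all <= log2(10)))
})

test_that("trait correlation matches cor.test and flags exact copies", {
  set.seed(30)
  expr <- matrix(rlnorm(10 * 30), 10, 30,
                 dimnames = list(paste0("g", 1:10), paste0("A", 1:30)))
  traits <- data.frame(accession = paste0("A", 1:30),
                       clove_number = expr[3, ] ,
                       bulb_weight = rnorm(30))
  expr[9, ] <- 4  # constant gene -> undefined correlation
  tc <- trait_correlation(expr, traits)
  expect_equal(tc$r[tc$gene == "g3" & tc$trait == "clove_number"], 1)
  expect_true(is.na(tc$r[tc$gene == "g9" & tc$trait == "bulb_weight"]))
  ct <- cor.test(expr[5, ], traits$bulb_weight)
  expect_equal(tc$r[tc$gene == "g5" & tc$trait == "bulb_weight"],
               unname(ct$estimate), tolerance = 1e-10)
  expect_equal(tc$p[tc$gene == "g5" & tc$trait == "bulb_weight"],
               ct$p.value, tolerance = 1e-10)
  # independent expression: |r| small on average, no extreme p excess
  expect_lt(mean(abs(tc$r[tc$trait == "bulb_weight"]), na.rm = TRUE), 0.35)
})

test_that("Fisher enrichment matches a hypergeometric brute force", {
  universe <- paste0("g", 1:1000)
  changed <- paste0("g", 1:100)
  correlated <- paste0("g", c(1:25, 901:925))
  en <- enrichment(changed, correlated, universe)
  a <- 25; b <- 75; cc <- 25; d <- 875
  expect_equal(en$p, brute_fisher2x2(a, b, cc, d), tolerance = 1e-10)
  expect_equal(unname(en$table["yes", "yes"]), a)

  # changed set equal to the correlated set: maximal enrichment
  same <- enrichment(changed, changed, universe)
  expect_lt(same$p, 1e-100)
  expect_true(same$significant)

  # random subsets are almost never significant at the 0.001 level
  set.seed(31)
  n_sig <- 0L
  for (i in 1:100) {
    rnd <- sample(universe, 100)
    if (enrichment(rnd, correlated, universe)$significant) n_sig <- n_sig + 1L
  }
  expect_lte(n_sig / 100, 0.01)
  expect_error(enrichment(changed, correlated, character()), "empty")
})
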