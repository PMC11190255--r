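# Normalization, RFU, scaling and the statistical battery.

test_that("relative fitness and fold change arithmetic, with safe references", {
  expect_equal(relativeFitness(500, 500), 100)
  expect_equal(relativeFitness(0, 500), 0)
  expect_equal(relativeFitness(403, 1500), 26.86667, tolerance = 1e-6)
  expect_true(is.na(relativeFitness(100, 0)))
  expect_true(is.na(relativeFitness(100, NA)))

  expect_equal(foldChange(7, 7), 0)
  expect_equal(foldChange(14, 7), 1)
  expect_equal(foldChange(3.45 * 200, 200), 2.45, tolerance = 1e-12)
  expect_true(is.na(foldChange(5, 0)))
})

test_that("RFU: background subtraction, OD normalization, clamping", {
  expect_equal(computeRFU(600, 100, 0.5), 1000)
  expect_equal(computeRFU(100, 100, 0.4), 0)
  expect_equal(computeRFU(50, 100, 0.4), 0)   # negative corrected -> clamp
  expect_error(computeRFU(600, 100, 0), "od595")
  # linearity in the corrected signal at fixed OD
  d <- seq(0, 500, by = 50)
  expect_equal(computeRFU(100 + d, 100, 0.25), d / 0.25)
})

test_that("RFU recovers planted lipid content linearly from a noiseless assay", {
  tr <- data.frame(strain_id = paste0("S", 1:20),
                   lipid_content = seq(0.02, 0.40, length.out = 20))
  a <- simulateLipidAssay(tr, replicates = 1, noise_cv = 0, seed = 4)
  rfu <- computeRFU(a$f_stained, a$f_background, a$od595)
  expect_equal(unname(cor(rfu, tr$lipid_content)), 1, tolerance = 1e-9)
})

test_that("maxAbsScale: column-wise division, invariances, degenerate input", {
  expect_equal(unname(maxAbsScale(cbind(c(2, 4, -8)))[, 1]), c(0.25, 0.5, -1))
  m <- cbind(a = c(-1, 0.5, 1), b = c(3, -6, 2))
  expect_equal(maxAbsScale(m)[, "a"], m[, "a"])       # already in [-1, 1]
  expect_equal(maxAbsScale(maxAbsScale(m)), maxAbsScale(m))  # idempotent
  expect_equal(maxAbsScale(7.3 * m), maxAbsScale(m))  # scale invariance
  expect_true(all(abs(maxAbsScale(m)) <= 1))
  expect_warning(z <- maxAbsScale(cbind(x = c(0, 0), y = c(1, 2))), "all-zero")
  expect_equal(unname(z[, "x"]), c(0, 0))
  expect_error(maxAbsScale(matrix(numeric(0), 0, 0)), "empty")
})

test_that("normality/variance gate routes as expected under null and alternative", {
  set.seed(101)
  g_null <- list(a = rnorm(100), b = rnorm(100))
  gate <- normalityVarianceGate(g_null)
  expect_gt(gate$levene_p, 0.05)
  skewed <- list(x = exp(rnorm(50)), y = rnorm(50))
  gate2 <- normalityVarianceGate(skewed)
  expect_lt(gate2$shapiro$p[gate2$shapiro$group == "x"], 0.05)
  expect_true(gate2$nonparametric)
  const <- normalityVarianceGate(list(c = rep(1, 10), d = rnorm(10)))
  expect_equal(const$shapiro$skipped[const$shapiro$group == "c"],
               "constant values")
  tiny <- normalityVarianceGate(list(e = c(1, 2)))
  expect_match(tiny$shapiro$skipped[1], "fewer than 3")
})

test_that("Mann-Whitney U: known exact values and the U_A + U_B identity", {
  mw <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p, 0.1)
  expect_true(mw$exact)
  # identical multisets: U near n^2/2, p = 1 (ties force the approximation)
  mw2 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw2$u, 4.5)
  expect_equal(mw2$p, 1)
  expect_false(mw2$exact)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(sample(2:8, 1)); b <- rnorm(sample(2:8, 1))
    ua <- mannWhitneyU(a, b)$u
    ub <- mannWhitneyU(b, a)$u
    expect_equal(ua + ub, length(a) * length(b))
  }
  expect_error(mannWhitneyU(numeric(0), 1:3), "nonempty")
})

test_that("exact Mann-Whitney p equals the full-enumeration oracle", {
  set.seed(33)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a <- rnorm(n1); b <- rnorm(n2)       # continuous draws: no ties
    ours <- mannWhitneyU(a, b)
    oracle <- oracle_mw_exact(a, b)
    expect_equal(ours$u, oracle$u)
    expect_equal(ours$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up oracle and its invariants", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bhAdjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    perm <- sample(length(p))
    expect_equal(bhAdjust(p[perm]), adj[perm])  # order invariance
  }
  expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("lipid-content tests: degenerate, symmetric and shifted groups", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  r <- lipidContentTests(same)
  expect_equal(r$anova_f, 0)
  expect_gte(r$kruskal_p, 0.99)
  set.seed(12)
  g1 <- rnorm(10, 10, 1); g2 <- rnorm(10, 13, 1)  # 3 SD shift
  r2 <- lipidContentTests(list(g1 = g1, g2 = g2))
  expect_lt(r2$anova_p, 0.01)
  expect_lt(r2$kruskal_p, 0.01)
  expect_error(lipidContentTests(list(a = 1:3)), "2 groups")
  expect_error(lipidContentTests(list(a = 1:3, b = 2)), ">= 2 observations")
})

test_that("comparison table: per-family BH, fold changes vs reference", {
  set.seed(9)
  d <- expand.grid(strain_id = c("REF", "S1", "S2"), rep = 1:4,
                   medium_id = c("m1", "m2"), stringsAsFactors = FALSE)
  d$variable <- "fitness"
  d$value <- rnorm(nrow(d), 100, 5)
  d$value[d$strain_id == "S1"] <- d$value[d$strain_id == "S1"] + 100
  tab <- compareToReference(d[, c("strain_id", "medium_id", "variable", "value")],
                            "REF")
  expect_setequal(unique(tab$strain_id), c("S1", "S2"))
  expect_true(all(tab$p_adj_bh >= tab$p_value - 1e-12))
  s1 <- tab[tab$strain_id == "S1", ]
  expect_true(all(s1$fold_change > 0.5))
  expect_true(all(s1$p_value < 0.05))
  # BH was applied within (variable, medium) families of 2 strains each
  fam <- tab[tab$medium_id == "m1", ]
  expect_equal(sort(fam$p_adj_bh),
               sort(oracle_bh(fam$p_value)), tolerance = 1e-12)
  expect_error(compareToReference(d, "missing_ref"), "not in data")
})
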