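# Media design, C/N adjustment and fermentation accounting.

test_that("mass-mode and single-acid media are simple proportions", {
  m <- designMedium(15, c(3, 1, 1), "mass")
  expect_equal(unname(acidConcentrations(m)), c(9, 3, 3))
  one <- designMedium(10, c(1, 0, 0), "mass")
  expect_equal(unname(acidConcentrations(one)), c(10, 0, 0))
  expect_error(designMedium(-5, c(1, 1, 1)), "> 0")
  expect_error(designMedium(10, c(0, 0, 0)), "not all zero")
})

test_that("carbon-mode design solves the linear system exactly", {
  m <- designMedium(25, c(3, 1, 1))
  oracle <- oracle_carbon_medium(25, c(3, 1, 1))
  expect_equal(unname(acidConcentrations(m)), oracle, tolerance = 1e-9)
  expect_equal(sum(acidConcentrations(m)), 25, tolerance = 1e-9)
  # the published-style approximate masses
  expect_equal(unname(acidConcentrations(m)), c(16.46, 4.51, 4.03),
               tolerance = 1e-3)
  r <- recoverRatio(m, "carbon")
  expect_equal(unname(r), c(3, 1, 1), tolerance = 1e-9)
})

test_that("carbon ratio round-trips for random designs", {
  set.seed(20)
  for (i in 1:100) {
    total <- runif(1, 5, 60)
    ratio <- sample(1:6, 3, replace = TRUE)
    m <- designMedium(total, ratio)
    rec <- recoverRatio(m, "carbon")
    expect_equal(unname(rec), ratio / min(ratio), tolerance = 1e-9)
    expect_equal(sum(acidConcentrations(m)), total, tolerance = 1e-9)
  }
})

test_that("ammonium sulphate for a target C/N: round-trip and proportionality", {
  m <- designMedium(25, c(3, 1, 1))
  ams <- ammoniumSulphateForCN(m, 200)
  expect_equal(ams, 0.259, tolerance = 2e-3)
  n_frac <- 2 * 14.007 / 132.14
  expect_equal(carbonContent(m) / (ams * n_frac), 200, tolerance = 1e-12)
  expect_equal(ammoniumSulphateForCN(m, 100), 2 * ams, tolerance = 1e-12)
  expect_error(ammoniumSulphateForCN(m, 0), "> 0")
})

test_that("consumption percentage arithmetic and clamping", {
  expect_equal(consumptionPercent(9, 9), 0)
  expect_equal(consumptionPercent(9, 2.7), 70)
  expect_warning(cl <- consumptionPercent(5, 5.5), "clamped")
  expect_equal(cl, 0)
  expect_error(consumptionPercent(0, 1), "> 0")
})

test_that("censored table values parse under both rules", {
  expect_equal(parseCensored(c("100", "<10", "23")), c(100, 0, 23))
  expect_equal(parseCensored(c("<10", "50"), "midpoint"), c(5, 50))
  expect_error(parseCensored(c("1", "abc")), "unparseable")
})

test_that("carbon-weighted totals: bounds and degenerate cases", {
  expect_equal(totalConsumption(c(100, 100, 100), c(3, 1, 1)), 100)
  expect_equal(totalConsumption(c(100, 0, 0), c(3, 1, 1)), 60)
  expect_equal(totalConsumption(c("100", "<10", "<10"), c(3, 1, 1)), 60)
  set.seed(21)
  for (i in 1:30) {
    pct <- runif(3, 0, 100)
    ratio <- sample(1:5, 3, replace = TRUE)
    tot <- totalConsumption(pct, ratio, digits = NULL)
    expect_gte(tot, min(pct))
    expect_lte(tot, max(pct))
  }
  # mass-weighted alternative via explicit weights
  expect_equal(totalConsumption(c(80, 40, 20), weights = c(9, 3, 3),
                                digits = NULL),
               (9 * 80 + 3 * 40 + 3 * 20) / 15)
})

test_that("lipid yield, inverse biomass utility and consumption rate", {
  expect_equal(lipidYield(25, 4, 10), 0.10)
  expect_equal(lipidYield(25, 8, 10), 0.20)             # linear in biomass
  expect_true(is.na(lipidYield(25, 4, 0)))
  # invert a printed-style triplet: lipid 29% w/w, 62% of 25 g/L consumed,
  # yield 0.12 -> biomass about 6.4 g/L
  consumed <- 0.62 * 25
  b <- biomassForYield(29, 0.12, consumed)
  expect_equal(b, 6.41, tolerance = 1e-2)
  expect_equal(lipidYield(29, b, consumed), 0.12, tolerance = 1e-12)

  expect_equal(consumptionRate(15, 100), 0.15)
  expect_equal(consumptionRate(0, 50), 0)
  expect_equal(consumptionRate(0.15 * 100, 100) * 100, 15)  # round-trip
  expect_error(consumptionRate(5, 0), "> 0")
})

test_that("fermentation summaries: constants, planted depletion, round-trip", {
  med <- designMedium(15, c(3, 1, 1))
  conc <- unname(acidConcentrations(med))
  flat <- data.frame(time_h = c(0, 50, 100),
                     acetic_gL = conc[1], propionic_gL = conc[2],
                     butyric_gL = conc[3], od600 = 1)
  s <- summarizeFermentation(flat, med)
  expect_equal(s$total_pct, 0)
  expect_equal(s$consumption_rate, 0)

  # acetic fully depleted, others untouched: carbon-weighted total = 60
  dep <- data.frame(time_h = c(0, 100),
                    acetic_gL = c(conc[1], 0), propionic_gL = conc[2],
                    butyric_gL = conc[3], od600 = c(1, 5))
  s2 <- summarizeFermentation(dep, med)
  expect_equal(s2$total_pct, 60)
  expect_equal(s2$acetic_pct, 100)

  # noiseless generator output round-trips through the summary
  tr <- data.frame(u_acetic = 0.12, u_propionic = 0.05, u_butyric = 0.02,
                   biomass_yield = 0.35)
  tc <- simulateFermentation(tr, med, duration_h = 100, dt_h = 1)
  s3 <- summarizeFermentation(tc, med, lipid_content = 20, biomass = 3)
  last <- tc[nrow(tc), ]
  expect_equal(s3$acetic_pct, 100 * (conc[1] - last$acetic_gL) / conc[1],
               tolerance = 1e-9, ignore_attr = TRUE)
  consumed <- sum(conc) - sum(last[, c("acetic_gL", "propionic_gL", "butyric_gL")])
  expect_equal(s3$consumed_gL, consumed, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(s3$yield_ls, 0.2 * 3 / consumed, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(s3$max_od600, max(tc$od600))

  off <- dep
  off$acetic_gL[1] <- conc[1] * 1.5
  expect_warning(summarizeFermentation(off, med), "deviate")
})
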