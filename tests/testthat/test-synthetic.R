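# Synthetic-data generator: closed-form identities, determinism, and the
# structural guarantees downstream stages rely on.

small_design <- function(...) {
  screenDesign(media = c("glucose", "APB_3_1_1"), density = 96L,
               replicates = 2L, interval_h = 0.5, duration_h = 48,
               noise_cv = 0, noise_floor_sd = 0, seed = 11L, ...)
}

test_that("noiseless viable curves equal the closed-form logistic; non-viable stay flat", {
  des <- small_design()
  truths <- make_small_truths(6, seed = 3, media = des$media)
  sim <- simulateScreen(des, truths)
  lay <- screenLayout(sim$screen)
  t <- screenTimes(sim$screen)
  sz <- screenSizes(sim$screen)
  g <- truths$growth
  for (i in seq_len(nrow(lay))) {
    p <- g[g$strain_id == lay$strain_id[i] & g$medium_id == lay$medium_id[i], ]
    expected <- if (p$viable) oracle_logistic(t, p$K, p$s0, p$r, p$t_mid)
                else rep(p$s0, length(t))
    expect_equal(unname(sz[, i]), expected, tolerance = 1e-12)
  }
  expect_true(any(!g$viable[g$medium_id == "APB_3_1_1"]))  # both cases exercised
})

test_that("logistic maximum slope occurs at the planted inflection time", {
  t <- seq(0, 96, by = 0.25)
  s <- logisticSize(t, K = 2000, s0 = 100, r = 0.2, t_mid = 40)
  slopes <- diff(s) / diff(t)
  t_star <- (t[which.max(slopes)] + t[which.max(slopes) + 1]) / 2
  expect_lt(abs(t_star - 40), 0.25)
})

test_that("identical seeds give identical output; different seeds differ", {
  des <- screenDesign(media = c("glucose", "APB_3_1_1"), density = 96L,
                      replicates = 2L, interval_h = 0.5, duration_h = 48,
                      noise_cv = 0.05, noise_floor_sd = 1, seed = 5L)
  s1 <- simulateScreen(des, make_small_truths(5, seed = 2, media = des$media))
  s2 <- simulateScreen(des, make_small_truths(5, seed = 2, media = des$media))
  expect_identical(screenSizes(s1$screen), screenSizes(s2$screen))
  des2 <- des; des2$seed <- 6L
  s3 <- simulateScreen(des2, make_small_truths(5, seed = 2, media = des$media))
  expect_false(identical(screenSizes(s1$screen), screenSizes(s3$screen)))
  expect_true(all(screenSizes(s1$screen) >= 0))
})

test_that("missing strain-medium parameters raise an error naming them", {
  des <- small_design()
  truths <- make_small_truths(3, seed = 1, media = des$media)
  truths$growth <- truths$growth[!(truths$growth$strain_id == "S02" &
                                     truths$growth$medium_id == "APB_3_1_1"), ]
  expect_error(simulateScreen(des, truths), "S02 on APB_3_1_1")
})

test_that("reference strain is present on every plate", {
  des <- screenDesign(media = c("glucose", "APB_3_1_1"), density = 96L,
                      replicates = 3L, interval_h = 1, duration_h = 48,
                      noise_cv = 0, seed = 1L)
  truths <- makeTruths(sprintf("S%03d", 1:120), media = des$media, seed = 1)
  sim <- simulateScreen(des, truths)
  lay <- screenLayout(sim$screen)
  per_plate <- tapply(lay$strain_id, lay$plate_id, function(s) "REF1" %in% s)
  expect_true(all(per_plate))
  expect_gt(length(unique(lay$plate_id)), length(des$media))  # overflow plates
})

test_that("lipid assay follows the stated signal model", {
  tr <- data.frame(strain_id = c("A", "B"), lipid_content = c(0.10, 0.20))
  a <- simulateLipidAssay(tr, replicates = 1, gain = 1e4, background = 50,
                          od_half_range = 0, noise_cv = 0, seed = 1)
  # zero lipid -> stained equals background
  z <- simulateLipidAssay(data.frame(strain_id = "Z", lipid_content = 0),
                          replicates = 2, noise_cv = 0, seed = 1)
  expect_equal(z$f_stained, z$f_background)
  # linearity: RFU ratio equals lipid ratio at equal OD
  rfu <- computeRFU(a$f_stained, a$f_background, a$od595)
  expect_equal(rfu[2] / rfu[1], 2, tolerance = 1e-12)
  # plug-in value: gain 1e4, lipid 0.15, OD 0.6, background 50 -> 50 + 900
  b <- simulateLipidAssay(data.frame(strain_id = "C", lipid_content = 0.15),
                          replicates = 1, gain = 1e4, background = 50,
                          od_mean = 0.6, od_half_range = 0, noise_cv = 0,
                          seed = 1)
  expect_equal(b$f_stained, 950, tolerance = 1e-9)
})

test_that("fermentation generator honors closed forms and acid preference", {
  med <- designMedium(9, c(1, 0, 0), "mass")
  still <- data.frame(u_acetic = 0, u_propionic = 0, u_butyric = 0,
                      biomass_yield = 0.3)
  tc0 <- simulateFermentation(still, med, duration_h = 50, dt_h = 1)
  expect_true(all(tc0$acetic_gL == 9) && all(tc0$od600 == tc0$od600[1]))

  one <- data.frame(u_acetic = 0.1, u_propionic = 0, u_butyric = 0,
                    biomass_yield = 0.3)
  tc1 <- simulateFermentation(one, med, duration_h = 120, dt_h = 1)
  expect_equal(min(tc1$time_h[tc1$acetic_gL <= 1e-12]), 90)  # 9 / 0.1 g/(L h)

  med3 <- designMedium(15, c(3, 1, 1))
  tr <- data.frame(u_acetic = 0.15, u_propionic = 0.06, u_butyric = 0.03,
                   biomass_yield = 0.35)
  tc3 <- simulateFermentation(tr, med3, duration_h = 400, dt_h = 1)
  t90 <- function(col) {
    init <- tc3[[col]][1]
    min(tc3$time_h[tc3[[col]] <= 0.1 * init])
  }
  expect_lt(t90("acetic_gL"), t90("propionic_gL"))
  expect_lt(t90("propionic_gL"), t90("butyric_gL"))
  # monotone decline, non-negative; OD non-decreasing
  for (cl in c("acetic_gL", "propionic_gL", "butyric_gL")) {
    expect_true(all(diff(tc3[[cl]]) <= 1e-12))
    expect_true(all(tc3[[cl]] >= 0))
  }
  expect_true(all(diff(tc3$od600) >= -1e-12))
  expect_error(simulateFermentation(tr, med3, duration_h = -1), "duration")
})

test_that("screen tables round-trip through delimited text", {
  des <- small_design()
  sim <- simulateScreen(des, make_small_truths(4, seed = 9, media = des$media))
  tabs <- screenTables(sim$screen)
  dir <- withr::local_tempdir()
  write.table(tabs$layout, file.path(dir, "lay.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(tabs$timecourse, file.path(dir, "tc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  back <- readColonyScreen(file.path(dir, "lay.tsv"), file.path(dir, "tc.tsv"))
  expect_equal(screenTimes(back), screenTimes(sim$screen))
  expect_equal(unname(screenSizes(back)), unname(screenSizes(sim$screen)),
               tolerance = 1e-6)
})
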