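test_that("elongation and expression rates follow their defining formulas", {
  expect_equal(elongation_rate(rep(2, 5), 3), c(NA, 0, 0, 0, 0))
  t <- seq(0, 30, 3)
  L <- 2 * exp(0.012 * t)
  expect_equal(elongation_rate(L, 3)[-1], rep(0.012, 10))
  # direct evaluation: 2.00 -> 2.06 um over 3 min
  expect_equal(elongation_rate(c(2, 2.06), 3)[2], log(2.06 / 2) / 3)
  expect_equal(elongation_rate(c(2, 2.06), 3)[2], 0.0098529, tolerance = 1e-5)
  expect_error(elongation_rate(c(2, -1), 3), "> 0")
  # division frames are NA
  el <- elongation_rate(c(2, 2.1, 1.05, 1.1), 3,
                        new_cell = c(TRUE, FALSE, TRUE, FALSE))
  expect_true(is.na(el[3]) && !is.na(el[4]))

  expect_equal(expression_rate(rep(7, 4), 3), c(NA, 0, 0, 0))
  expect_equal(expression_rate(c(100, 103), 3)[2], 1)
})

test_that("promoter activity is exactly I*elongation + expression rate", {
  set.seed(1)
  I <- runif(40, 50, 150); L <- cumprod(c(1, exp(rnorm(39, 0.03, 0.01))))
  act <- promoter_activity(I, L, 3)
  el <- elongation_rate(L, 3)
  expect_identical(act, I * el + expression_rate(I, 3))
  # steady exponential growth, constant intensity -> I0 * g
  t <- seq(0, 60, 3)
  act2 <- promoter_activity(rep(80, length(t)), exp(0.012 * t), 3)
  expect_equal(act2[-1], rep(80 * 0.012, length(t) - 1))
  # growth arrest, intensity rising at slope s -> activity = s
  act3 <- promoter_activity(100 + 2.5 * t, rep(1.5, length(t)), 3)
  expect_equal(act3[-1], rep(2.5, length(t) - 1))
})

test_that("population peak/steady match brute-force oracles and conventions", {
  # single-trace dataset: the mean trace is the trace itself
  lay <- channel_layout(n_trenches = 1, cells_per_trench = 1)
  ds <- generate_tracks("planted", lay,
                        templates = default_regulon_templates()["hcp"],
                        noise = noise_off(1))
  # replace the window with a known ramp 1..27 (t = 12..90)
  sel <- ds$records$time >= 12 & ds$records$time <= 90
  ds$records$I_gfp[sel] <- 1:27
  expect_equal(population_peak(ds, "hcp"), quantile_oracle(1:27, 0.9))
  expect_equal(population_peak(ds, "hcp"), 24.4)

  # constant trace: peak = steady = basal = c
  ds$records$I_gfp <- 42
  w <- analysis_windows()
  expect_equal(population_peak(ds, "hcp", w), 42)
  expect_equal(population_steady(ds, "hcp", w), 42)
  expect_equal(basal_level(ds, "hcp"), 42)

  # pooled convention on a multi-trace dataset equals the sorted oracle
  ds2 <- small_planted_ds(genes = "katG", n_trenches = 4,
                          noise = noise_model(seed = 2))
  rec <- ds2$records
  pooled <- rec$I_gfp[rec$time >= 12 & rec$time <= 90]
  expect_equal(population_peak(ds2, "katG", method = "pooled"),
               quantile_oracle(pooled, 0.9))
})

test_that("planted sustained_up ratio is recovered noiselessly", {
  tm <- default_regulon_templates()[["katG"]]
  tm$t_peak_sd <- 0     # no per-cell timing spread: exact recovery
  ds <- generate_tracks("planted",
                        channel_layout(n_trenches = 3,
                                       cells_per_trench = 1),
                        templates = list(tm), noise = noise_off(1))
  r <- population_peak(ds, "katG") / population_steady(ds, "katG")
  expect_equal(r, 3, tolerance = 0.02)
})

test_that("single-cell peak statistics follow their windows", {
  t <- seq(-30, 180, 3)
  rising <- 10 + t                       # monotone: last frame <= 100 wins
  expect_equal(cell_time_to_peak(t, rising), 99)
  flat <- rep(5, length(t))              # flat: tie broken to first frame
  expect_equal(cell_time_to_peak(t, flat), 3)
  expect_equal(cell_peak(t, flat), 0)
  pulse <- exp(-(t - 30)^2 / 200)
  expect_equal(cell_time_to_peak(t, pulse), 30)
  # parabolic refinement reproduces an off-grid vertex
  pulse2 <- -(t - 31)^2
  expect_equal(cell_time_to_peak(t, pulse2, interpolate = TRUE), 31)
  expect_error(cell_time_to_peak(t[t < 0], rising[t < 0]), "no frames")
})

test_that("coefficient of variation uses the sample convention", {
  expect_equal(coefficient_of_variation(rep(3, 10)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sd(c(1, 3)) / 2)
  expect_error(coefficient_of_variation(1), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero")
})

test_that("gene-to-gene CV peaks in the transient window", {
  ds <- small_planted_ds(genes = c("katG", "grxA", "fhuF", "hcp"),
                         n_trenches = 20,
                         noise = noise_model(seed = 6, cell_cv = 0.1))
  cv <- gene_to_gene_cv(ds)
  cv_pre <- mean(cv$cv[cv$time <= 0])
  cv_peak <- max(cv$cv[cv$time >= 12 & cv$time <= 90])
  cv_steady <- mean(cv$cv[cv$time >= 150])
  expect_gt(cv_peak, cv_steady)
  expect_gt(cv_steady, cv_pre)
})

test_that("spatial profiles are frontier-normalised and match hand sums", {
  # toy 2-trench table at one frame
  rec <- data.frame(
    trench_id = c(1, 1, 1, 2, 2, 2), barrier_count = c(0, 1, 2, 0, 1, 2),
    cell_id = letters[1:6], lineage_id = letters[1:6], gene = "g",
    time = 30, length_um = 1, area_um2 = 1,
    I_gfp = c(10, 8, 5, 20, 12, 8))
  ds <- structure(list(records = rec,
                       manifest = list(layout = list(frame_interval = 3))),
                  class = "track_dataset")
  prof <- relative_spatial_profile(ds, "g", c(0, 60))
  expect_equal(prof$ratio, c(1, mean(c(8 / 10, 12 / 20)),
                             mean(c(5 / 10, 8 / 20))))
  # uniform expression: all ratios 1
  rec$I_gfp <- 7
  ds$records <- rec
  expect_equal(relative_spatial_profile(ds, "g", c(0, 60))$ratio,
               rep(1, 3))
  # missing frontier cell -> trench skipped with a warning
  ds$records <- rec[rec$barrier_count > 0 | rec$trench_id == 1, ]
  expect_warning(relative_spatial_profile(ds, "g", c(0, 60)), "skipped")
})

test_that("cross-correlation is exact at lag 0 and near zero for noise", {
  set.seed(8)
  x <- matrix(rnorm(40 * 120), 40)
  cc_self <- cross_correlation(x, x, max_lag = 4, detrend_window = 0)
  expect_equal(cc_self$corr[cc_self$lag_min == 0], 1)
  y <- matrix(rnorm(40 * 120), 40)
  cc_null <- cross_correlation(x, y, max_lag = 4, detrend_window = 0)
  expect_lt(abs(cc_null$corr[cc_null$lag_min == 0]),
            3 / sqrt(40 * 120))
  expect_error(cross_correlation(rnorm(10), rnorm(10), max_lag = 6),
               "too short")
})

test_that("window statistics ignore frames outside their windows", {
  ds <- small_planted_ds(genes = "katG", n_trenches = 5,
                         noise = noise_model(seed = 3))
  w <- analysis_windows()
  peak0 <- population_peak(ds, "katG", w)
  steady0 <- population_steady(ds, "katG", w)
  aw0 <- activity_window_means(ds, w)
  # level windows: poison every frame outside the declared window with a
  # sentinel; the statistic must not move
  poison2 <- ds
  out_peak <- with(poison2$records, time < 12 | time > 90)
  poison2$records$I_gfp[out_peak] <- 1e9
  expect_equal(population_peak(poison2, "katG", w), peak0)
  poison3 <- ds
  poison3$records$I_gfp[poison3$records$time < 150] <- 1e9
  expect_equal(population_steady(poison3, "katG", w), steady0)
  # activity windows: poisoning the unused mid-gap frames leaves the
  # basal/peak/steady activity means untouched
  poison4 <- ds
  gap <- with(poison4$records, time %in% seq(66, 114, 3) | time > 183)
  poison4$records$I_gfp[gap] <- 1e9
  aw4 <- activity_window_means(poison4, w)
  expect_equal(aw4$basal, aw0$basal)
  expect_equal(aw4$peak, aw0$peak)
  expect_equal(aw4$steady, aw0$steady)
})
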