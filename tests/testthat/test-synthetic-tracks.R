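test_that("planted traces honour their construction targets", {
  tmpl <- default_regulon_templates()
  times <- seq(-120, 360, by = 3)

  # sustained_up: noiseless peak/steady ratio equals the planted ratio
  for (g in c("katG", "grxA")) {
    cal <- calibrate_template(tmpl[[g]])
    expect_equal(cal$peak / cal$steady, tmpl[[g]]$peak_over_steady,
                 tolerance = 0.02)
    expect_equal(cal$peak / tmpl[[g]]$basal, tmpl[[g]]$amplitude,
                 tolerance = 0.02)
  }

  # unregulated gene: flat baseline, passive level pulse, flat activity
  tr <- planted_trace(tmpl[["hcp"]], times)
  basal <- tmpl[["hcp"]]$basal
  expect_equal(tr$level[times <= 0], rep(basal, sum(times <= 0)),
               tolerance = 1e-8)
  expect_gt(max(tr$level), basal * 1.15)            # passive pulse
  expect_equal(max(abs(tr$activity / tr$activity[1] - 1)), 0,
               tolerance = 1e-8)                    # activity stays flat

  # transient pulse is back at baseline activity well before the steady
  # window
  trd <- planted_trace(tmpl[["tdn01"]], times)
  expect_lt(max(abs(trd$activity[times >= 115] /
                      trd$activity[1] - 1)), 1e-3)
  expect_error(planted_trace(tmpl[["hcp"]], seq(0, 60, 3)),
               "baseline")
})

test_that("template validation rejects inconsistent categories", {
  expect_error(planted_template("x", "sustained_up"), "dynamics")
  expect_error(planted_template("x", "none", dynamics = "pulsatile"),
               "cannot carry")
  expect_error(planted_template("x", "sustained_down", amplitude = 1.2),
               "amplitude")
  expect_error(planted_template("x", "transient_up", amplitude = 0.5),
               "amplitude")
})

test_that("generated datasets have the right shape and are seed-deterministic", {
  lay <- channel_layout(n_trenches = 4, cells_per_trench = 3)
  tmpl <- default_regulon_templates()[c("katG", "hcp")]
  ds1 <- generate_tracks("planted", lay, templates = tmpl,
                         noise = noise_model(seed = 9))
  ds2 <- generate_tracks("planted", lay, templates = tmpl,
                         noise = noise_model(seed = 9))
  expect_identical(ds1$records, ds2$records)
  # 2 genes x 4 trenches x 3 cells x 161 frames
  expect_equal(nrow(ds1$records), 2 * 4 * 3 * 161)
  # barrier counts contiguous 0..cells-1 within every trench-frame
  bc <- with(ds1$records[ds1$records$gene == "katG", ],
             tapply(barrier_count, paste(trench_id, time),
                    function(b) identical(sort(b), 0:2)))
  expect_true(all(bc))
  # ground truth lives in the manifest, not the table
  expect_false("category" %in% names(ds1$records))
  expect_equal(ds1$manifest$ground_truth$katG$category, "sustained_up")
})

test_that("noise-free frontier traces equal the template exactly", {
  lay <- channel_layout(n_trenches = 2, cells_per_trench = 1)
  tmpl <- default_regulon_templates()["fhuF"]
  ds <- generate_tracks("planted", lay, templates = tmpl,
                        noise = noise_off(3))
  rec <- ds$records[ds$records$trench_id == 1, ]
  tr <- planted_trace(tmpl[[1]], layout_times(lay))
  expect_equal(rec$I_gfp, tr$level)
})

test_that("division keeps lengths bounded and lineages form a forest", {
  lay <- channel_layout(n_trenches = 6, cells_per_trench = 2)
  ds <- generate_tracks("planted", lay,
                        templates = default_regulon_templates()["hcp"],
                        noise = noise_model(seed = 2))
  rec <- ds$records
  # threshold is 2 x birth (~1 um) with 5% noise; no cell can pass 2x that
  expect_lt(max(rec$length_um), 4.2)
  expect_gt(min(rec$length_um), 0)
  # each cell id belongs to exactly one lineage
  expect_true(all(tapply(rec$lineage_id, rec$cell_id,
                         function(l) length(unique(l)) == 1)))
  # lineages are anchored to one trench & position
  expect_true(all(tapply(rec$barrier_count, rec$lineage_id,
                         function(b) length(unique(b)) == 1)))
})

test_that("mechanistic tracks show weaker growth arrest deeper in the trench", {
  p <- oxy_params()
  lay <- channel_layout(n_trenches = 8, cells_per_trench = 3,
                        t_pre = 30, t_post = 120)
  ds <- generate_tracks("mechanistic", lay,
                        noise = noise_model(seed = 4, length_cv = 0),
                        params = p, protocol = protocol_step(100),
                        genes = list(constitutive_gene(p)),
                        attenuation = 0.3)
  rec <- ds$records
  rec <- rec[rec$time > 0 & rec$time <= 60, ]
  el <- do.call(rbind, lapply(split(rec, rec$lineage_id), function(s) {
    s <- s[order(s$time), ]
    newc <- c(TRUE, s$cell_id[-1] != s$cell_id[-nrow(s)])
    data.frame(bc = s$barrier_count[1],
               el = mean(elongation_rate(s$length_um, 3, newc), na.rm = TRUE))
  }))
  mean_el <- tapply(el$el, el$bc, mean)
  expect_true(all(diff(mean_el) > 0))   # interior cells less arrested
})

test_that("track CSV round-trips exactly and reports malformed input", {
  ds <- small_planted_ds(genes = "hcp", n_trenches = 2,
                         noise = noise_model(seed = 5))
  path <- file.path(tempdir(), "tracks_roundtrip.csv")
  write_tracks(ds, path)
  back <- read_tracks(path)
  expect_equal(back$records, ds$records)
  expect_equal(back$manifest$mode, "planted")
  # write(read(write)) is byte-identical
  path2 <- file.path(tempdir(), "tracks_roundtrip2.csv")
  write_tracks(back, path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))

  # missing required column is named in the error
  rec <- read.csv(path)
  rec$length_um <- NULL
  path3 <- file.path(tempdir(), "tracks_broken.csv")
  write.csv(rec, path3, row.names = FALSE)
  expect_error(read_tracks(path3), "length_um")

  # ragged row is reported with its line number
  lines <- readLines(path)
  lines[5] <- paste(lines[5], "extra", sep = ",")
  path4 <- file.path(tempdir(), "tracks_ragged.csv")
  writeLines(lines, path4)
  expect_error(read_tracks(path4), "line 5")
  expect_error(read_tracks(file.path(tempdir(), "absent.csv")),
               "no such file")
})

test_that("dual-reporter fluctuations share exactly the planted fraction", {
  tm <- default_regulon_templates()[["grxA"]]
  lay <- channel_layout(n_trenches = 25, cells_per_trench = 1)
  corr_at <- function(sf, seed) {
    nz <- noise_model(meas_cv = 0, ou_cv = 0.15, shared_fraction = sf,
                      cell_cv = 0, length_cv = 0, seed = seed)
    dd <- generate_dual_tracks(tm, tm, lay, noise = nz)
    r <- dd$records[dd$records$time >= 150, ]
    a <- do.call(rbind, lapply(split(r, r$trench_id), `[[`, "I_yfp"))
    b <- do.call(rbind, lapply(split(r, r$trench_id), `[[`, "I_cfp"))
    cc <- cross_correlation(a, b, max_lag = 5)
    cc$corr[cc$lag_min == 0]
  }
  expect_equal(corr_at(1, 3), 1, tolerance = 1e-10)
  expect_lt(corr_at(0, 3), 0.5)
  expect_gt(corr_at(0.8, 3), corr_at(0, 3))
})
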