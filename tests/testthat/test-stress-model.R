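test_that("growth inhibition function has the required Hill properties", {
  p <- oxy_params()
  expect_equal(growth_rate(0, p), 0.012)
  expect_equal(growth_rate(p$K_g, p), p$g_max / 2)
  expect_lt(growth_rate(1e6, p), 1e-10)
  h <- c(0, 1e-4, 1e-3, 1e-2, 1, 100)
  expect_true(all(diff(growth_rate(h, p)) <= 0))
  expect_error(growth_rate(-1, p))
})

test_that("derivatives reproduce dilution, half-saturation and fixed points", {
  p <- oxy_params()
  genes <- list(gene_spec("bare", R_basal = 0, K_ind = 0, K_D = 1),
                constitutive_gene(p))
  st <- c(OxyR_red = 1, GrxA = 0, KatG = 0, AhpC = 0, H2O2_cell = 0,
          n = 0, lnL = 0, expr_bare = 5,
          expr_constitutive = p$R_constitutive / p$g_max)
  dv <- oxy_derivatives(st, 0, p, genes)
  # OxyR fully reduced, no production: pure dilution at g_max
  expect_equal(dv[["expr_bare"]], -p$g_max * 5)
  # constitutive gene at its fixed point R/g
  expect_equal(dv[["expr_constitutive"]], 0, tolerance = 1e-12)

  # occupancy half-saturation: OxyR_ox = K_D gives induction K_ind / 2
  g1 <- list(gene_spec("r", R_basal = 0, K_ind = 8, K_D = 0.25))
  st2 <- st1 <- c(OxyR_red = 0.75, GrxA = 0, KatG = 0, AhpC = 0,
                  H2O2_cell = 0, n = 0, lnL = 0, expr_r = 0)
  dv1 <- oxy_derivatives(st1, 0, p, g1)
  expect_equal(dv1[["expr_r"]], 8 / 2)
})

test_that("basal steady state matches the closed-form fixed points", {
  p <- oxy_params()
  genes <- list(constitutive_gene(p), gene_spec("rep_down"))
  st <- basal_steady_state(p, genes)
  # conservation bound and non-negativity
  expect_true(st[["OxyR_red"]] <= p$OxyR_total)
  expect_true(all(st >= 0))
  # plasmid and constitutive fixed points R/g within 1%
  expect_equal(st[["n"]], p$R_n / p$g_max, tolerance = 0.01)
  expect_equal(st[["expr_constitutive"]], p$R_constitutive / p$g_max,
               tolerance = 0.01)
  # reporter with near-negligible occupancy
  expect_equal(st[["expr_rep_down"]], 4 / p$g_max, tolerance = 0.01)
  # AhpC fixed point is exact once induction is disabled
  p0 <- oxy_params(Kind_AhpC = 0)
  st0 <- basal_steady_state(p0, genes)
  expect_equal(st0[["AhpC"]], p0$R_ahpC_basal / p0$g_max, tolerance = 1e-3)
})

test_that("an untreated simulation stays at basal; a step produces one
           interior intracellular H2O2 spike", {
  p <- oxy_params()
  genes <- list(constitutive_gene(p), gene_spec("rep_down"))
  tr0 <- simulate_regulon(p, protocol_none(), genes,
                          t_start = 0, t_end = 300)
  expect_equal(max(abs(tr0$expr_constitutive - p$R_constitutive / p$g_max)),
               0, tolerance = 1e-4)
  expect_equal(max(abs(tr0$expr_rep_down / tr0$expr_rep_down[1] - 1)),
               0, tolerance = 1e-6)

  tr <- simulate_regulon(p, protocol_step(100), genes,
                         t_start = -30, t_end = 240)
  h <- tr$H2O2_cell
  i_max <- which.max(h)
  expect_gt(tr$time[i_max], 0)
  expect_lt(tr$time[i_max], 60)
  expect_gt(max(h), 100 * h[tr$time == 0])      # a genuine spike
  # all state variables stay non-negative, OxyR_red within [0, total]
  st_cols <- c("OxyR_red", "GrxA", "KatG", "AhpC", "H2O2_cell", "n")
  expect_true(all(as.matrix(as.data.frame(tr)[st_cols]) >= 0))
  expect_true(all(tr$OxyR_red <= p$OxyR_total + 1e-8))
})

test_that("katG knockout zeroes its expression and is idempotent", {
  p <- oxy_params()
  k1 <- knockout_katG(p)
  expect_identical(k1$Kind_KatG, 0)
  expect_identical(k1$R_katG_basal, 0)
  k2 <- knockout_katG(k1)
  expect_identical(k1, k2)
  other <- setdiff(names(p), c("Kind_KatG", "R_katG_basal"))
  expect_identical(p[other], k1[other])
})

test_that("dose response is monotone for an upregulated reporter and
           steeper for the high-K_D promoter", {
  p <- oxy_params()
  hi <- gene_spec("hiKD", R_basal = 0.5, K_ind = 3, K_D = 0.1)
  lo <- gene_spec("loKD", R_basal = 0.5, K_ind = 0.3, K_D = 0.01)
  d_hi <- dose_response(p, hi, c(0, 25, 50, 100), t_end = 300)
  d_lo <- dose_response(p, lo, c(0, 25, 50, 100), t_end = 300)
  expect_equal(d_hi$peak_rel[1], 1, tolerance = 1e-6)   # no perturbation
  expect_true(all(diff(d_hi$peak_level) > 0))           # monotone in dose
  s_hi <- dose_sensitivity(d_hi$conc[-1], d_hi$peak_rel[-1],
                           d_hi$steady_rel[-1])
  s_lo <- dose_sensitivity(d_lo$conc[-1], d_lo$peak_rel[-1],
                           d_lo$steady_rel[-1])
  expect_gt(s_hi$peak_slope, s_lo$peak_slope)
})

test_that("trench profile attenuates the external dose geometrically", {
  p <- oxy_params()
  genes <- list(gene_spec("r", R_basal = 0.5, K_ind = 3, K_D = 0.1))
  prof <- trench_profile(p, genes, n_positions = 3,
                         attenuation_per_cell = 0.3,
                         protocol = protocol_step(100),
                         t_start = -12, t_end = 60)
  expect_length(prof, 3)
  # position k sees (1 - 0.3)^k of the frontier dose
  expect_equal(h2o2_at(attr(prof[[3]], "protocol"), 10), 100 * 0.49)
  # attenuation 0: all positions identical to the frontier
  prof0 <- trench_profile(p, genes, n_positions = 2,
                          attenuation_per_cell = 0,
                          protocol = protocol_step(100),
                          t_start = -12, t_end = 30)
  expect_equal(prof0[[1]]$expr_r, prof0[[2]]$expr_r)
})

test_that("protocol construction and lookup behave", {
  pr <- protocol_graded(c(25, 50, 100), c(0, 60, 120))
  expect_equal(h2o2_at(pr, c(-10, 5, 59, 61, 200)), c(0, 25, 25, 50, 100))
  expect_error(treatment_protocol(data.frame(start = c(0, 0),
                                             conc = c(1, 2))),
               "strictly increasing")
  expect_error(treatment_protocol(data.frame(start = 10, conc = 5)),
               "at or before")
  expect_error(protocol_step(-5))
})
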