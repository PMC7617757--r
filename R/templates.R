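#' Phenomenological expression template for planted synthetic data
#'
#' A planted template describes one gene's ground-truth regulation under a
#' step treatment at t = 0: a promoter-activity time course (step up/down,
#' transient pulse/dip, or flat) on top of a shared transient growth-arrest
#' profile.  The expression level is the integral of activity minus
#' growth dilution, so even "down" and "none" templates show the passive
#' expression pulse caused by the arrest.
#'
#' For upregulated categories \code{amplitude} is the fold-change of the
#' expression level over basal at the peak and \code{peak_over_steady} the
#' ratio of the population peak statistic (90th percentile of the level in
#' the 12-90 min window) to the steady-state level (mean from 150 min on);
#' the activity shape is calibrated so the noiseless level reproduces both
#' within 2\%.  For downregulated categories \code{amplitude} (< 1) is the
#' fold-change of promoter activity at the trough.
#'
#' @param gene gene label.
#' @param category one of \code{"sustained_up"}, \code{"transient_up"},
#'   \code{"sustained_down"}, \code{"transient_down"}, \code{"none"}.
#' @param dynamics \code{"pulsatile"}, \code{"gradual"} or \code{"na"}
#'   (only upregulated categories carry dynamics).
#' @param peak_over_steady target peak/steady ratio of the noiseless level
#'   (sustained_up only).
#' @param t_peak_mean,t_peak_sd mean and sd of the single-cell level peak
#'   time, min (categories with a transient peak).
#' @param amplitude fold-change at peak (up, > 1) or activity fold at the
#'   trough (down, < 1).
#' @param basal basal expression level, a.u.
#' @param dose_sens exponent of the dose scaling of the planted effect
#'   size (response proportional to (dose/100)^dose_sens); pulsatile genes
#'   are more dose-sensitive than gradually responding genes.
#' @return Object of class \code{planted_template}.
#' @export
planted_template <- function(gene, category, dynamics = "na",
                             peak_over_steady = 3,
                             t_peak_mean = 25.7, t_peak_sd = 4.7,
                             amplitude = 3, basal = 300,
                             dose_sens = NULL) {
  category <- match.arg(category, c("sustained_up", "transient_up",
                                    "sustained_down", "transient_down",
                                    "none"))
  dynamics <- match.arg(dynamics, c("pulsatile", "gradual", "na"))
  up <- category %in% c("sustained_up", "transient_up")
  if (category == "sustained_up" && dynamics == "na") {
    stop("sustained_up templates must declare pulsatile or gradual dynamics")
  }
  if (!up && dynamics != "na") {
    stop(sprintf("category '%s' cannot carry '%s' dynamics",
                 category, dynamics))
  }
  if (peak_over_steady <= 0) stop("peak_over_steady must be > 0")
  if (up && amplitude <= 1) stop("up categories need amplitude > 1")
  if (grepl("down", category) && (amplitude <= 0 || amplitude >= 1)) {
    stop("down categories need activity amplitude in (0, 1)")
  }
  if (basal <= 0) stop("basal must be > 0")
  if (is.null(dose_sens)) {
    dose_sens <- switch(dynamics, pulsatile = 1, gradual = 0.5, 0.7)
  }
  structure(list(gene = gene, category = category, dynamics = dynamics,
                 peak_over_steady = peak_over_steady,
                 t_peak_mean = t_peak_mean, t_peak_sd = t_peak_sd,
                 amplitude = amplitude, basal = basal,
                 dose_sens = dose_sens),
            class = "planted_template")
}

#' Shared growth-arrest profile of planted data
#'
#' Growth is at \code{g_max} before treatment, drops by \code{depth} at
#' t = 0 and recovers with half-time \code{t_half} (default 30 min),
#' mimicking the transient growth inhibition seen at the onset of H2O2
#' stress.
#'
#' @param t time(s), min.
#' @param g_max unstressed growth rate, min^-1.
#' @param depth fractional arrest depth at t = 0.
#' @param t_half recovery half-time, min.
#' @return growth rate(s), min^-1.
#' @export
growth_arrest_profile <- function(t, g_max = 0.012, depth = 0.9,
                                  t_half = 30) {
  # the treatment-start frame t = 0 still belongs to the baseline
  ifelse(t <= 0, g_max, g_max * (1 - depth * 2^(-t / t_half)))
}

# activity shape: a(t) = a0 * (1 + (s - 1) * S(t) + p * P(t)), floored at 0
# S: saturating induction step; P: gamma-shaped pulse peaking at t_pulse
template_activity <- function(t, a0, s, p, t_pulse, tau_ind = 20,
                              kappa = 4) {
  S <- ifelse(t < 0, 0, 1 - exp(-pmax(t, 0) / tau_ind))
  x <- pmax(t, 0) / t_pulse
  P <- ifelse(t <= 0, 0, x^kappa * exp(kappa * (1 - x)))
  pmax(a0 * (1 + (s - 1) * S + p * P), 0)
}

# exact exponential-integrator step for dL/dt = a(t) - g(t) L on a fine grid
integrate_level <- function(times, activity, growth, L0) {
  n <- length(times)
  L <- numeric(n)
  L[1] <- L0
  dt <- diff(times)
  for (i in seq_len(n - 1L)) {
    g <- (growth[i] + growth[i + 1L]) / 2
    a <- (activity[i] + activity[i + 1L]) / 2
    e <- exp(-g * dt[i])
    L[i + 1L] <- if (g > 1e-12) L[i] * e + a * (1 - e) / g else
      L[i] + a * dt[i]
  }
  L
}

# Solve template shape parameters so the noiseless level hits the planted
# peak (amplitude * basal) and steady (amplitude * basal / ratio) targets,
# and (for peaked categories) so the level peaks at t_peak_mean.
# Nearly linear in (s, p): a short damped-Newton iteration suffices.
calibrate_template <- function(template, g_max = 0.012, depth = 0.9,
                               t_half = 30, t_pre = 120, t_post = 360,
                               dt_fine = 0.5) {
  tm <- template
  tfine <- seq(-t_pre, t_post, by = dt_fine)
  growth <- growth_arrest_profile(tfine, g_max, depth, t_half)
  a0 <- tm$basal * g_max
  frames <- seq(-t_pre, t_post, by = 3)
  w_peak <- c(12, 90)

  eval_shape <- function(s, p, t_pulse) {
    act <- template_activity(tfine, a0, s, p, t_pulse)
    lvl <- integrate_level(tfine, act, growth, tm$basal)
    lf <- approx(tfine, lvl, frames)$y
    peak <- quantile(lf[frames >= w_peak[1] & frames <= w_peak[2]], 0.9,
                     type = 7, names = FALSE)
    steady <- mean(lf[frames >= 150])
    post <- tfine > 0
    t_pk <- tfine[post][which.max(lvl[post])]
    list(act = act, lvl = lvl, peak = peak, steady = steady, t_pk = t_pk)
  }

  s <- 1; p <- 0; t_pulse <- max(tm$t_peak_mean * 0.8, 5)
  if (tm$category == "none") {
    # flat activity
  } else if (tm$category == "sustained_down") {
    s <- tm$amplitude
  } else if (tm$category %in% c("transient_down", "transient_up")) {
    # activity pulse/dip centred on the planted peak time so that it falls
    # inside the peak-activity window; no level-peak alignment (the level
    # maximum of weak transients is dominated by the passive pulse)
    p <- tm$amplitude - 1
    t_pulse <- max(tm$t_peak_mean * 0.85, 8)
  } else { # sustained_up: solve (s, p) for the level targets, t_pulse for
    # the level peak time
    target <- c(tm$amplitude * tm$basal,
                tm$amplitude * tm$basal / tm$peak_over_steady)
    s <- max(tm$amplitude / tm$peak_over_steady, 0.05); p <- 0.5
    solve_sp <- function(s, p, t_pulse) {
      for (iter in 1:40) {
        f0 <- eval_shape(s, p, t_pulse)
        r <- c(f0$peak, f0$steady) - target
        if (max(abs(r) / target) < 2e-4) break
        hs <- 1e-3; hp <- 1e-3
        fs <- eval_shape(s + hs, p, t_pulse)
        fp <- eval_shape(s, p + hp, t_pulse)
        J <- cbind(c(fs$peak - f0$peak, fs$steady - f0$steady) / hs,
                   c(fp$peak - f0$peak, fp$steady - f0$steady) / hp)
        step <- tryCatch(solve(J, r), error = function(e) r * 0)
        lim <- c(max(abs(s) / 2, 0.5), max(abs(p) / 2, 0.5))
        step <- pmin(pmax(step, -lim), lim)       # damped Newton
        s <- max(s - step[1], 1e-3)
        p <- max(p - step[2], 0)
      }
      list(s = s, p = p, t_pk = f0$t_pk)
    }
    for (k in 1:10) {
      fit <- solve_sp(s, p, t_pulse)
      s <- fit$s; p <- fit$p
      err <- tm$t_peak_mean - fit$t_pk
      if (abs(err) <= dt_fine) break
      t_pulse <- min(max(t_pulse + 0.7 * err, 4), 80)
    }
  }
  f0 <- eval_shape(s, p, t_pulse)
  list(template = tm, s = s, p = p, t_pulse = t_pulse,
       t_fine = tfine, activity = f0$act, level = f0$lvl,
       growth = growth, t_peak_level = f0$t_pk,
       peak = f0$peak, steady = f0$steady,
       a0 = a0, g_max = g_max, depth = depth, t_half = t_half)
}

#' Scale a planted template's effect size with treatment dose
#'
#' The planted regulation magnitude scales as \code{(dose/100)^dose_sens};
#' the peak/steady ratio class of the gene is unchanged, so across doses
#' the (steady, peak) points of a gene move along a line through the
#' origin with slope equal to the class ratio.
#'
#' @param template a \code{\link{planted_template}}.
#' @param dose external H2O2 dose, uM (reference 100).
#' @return rescaled \code{planted_template}.
#' @export
scale_template_dose <- function(template, dose) {
  if (dose < 0) stop("dose must be >= 0")
  f <- (dose / 100)^template$dose_sens
  if (template$category %in% c("sustained_up", "transient_up")) {
    template$amplitude <- 1 + (template$amplitude - 1) * f
  } else if (template$category != "none") {
    template$amplitude <- 1 - (1 - template$amplitude) * f
  }
  template
}

#' Noiseless planted trace for one cell
#'
#' Evaluates a template on a frame grid, optionally warping the
#' post-treatment time axis so the expression level peaks at a given
#' per-cell time (used to plant single-cell peak-time distributions).
#'
#' @param template a \code{\link{planted_template}}.
#' @param times frame times, min (must include a t < 0 baseline).
#' @param t_peak optional per-cell level peak time, min.
#' @param calib optional precomputed \code{calibrate_template} result.
#' @return data.frame with \code{time}, \code{level}, \code{activity},
#'   \code{growth}.
#' @export
planted_trace <- function(template, times, t_peak = NULL, calib = NULL) {
  if (!any(times < 0)) stop("times must include a pre-treatment baseline")
  if (is.null(calib)) calib <- calibrate_template(template)
  warp <- if (!is.null(t_peak) && calib$t_peak_level > 0) {
    calib$t_peak_level / t_peak
  } else 1
  q <- ifelse(times > 0, times * warp, times)
  q <- pmin(pmax(q, min(calib$t_fine)), max(calib$t_fine))
  data.frame(
    time = times,
    level = approx(calib$t_fine, calib$level, q)$y,
    activity = approx(calib$t_fine, calib$activity, q)$y,
    growth = growth_arrest_profile(times, calib$g_max, calib$depth,
                                   calib$t_half)
  )
}

#' The default 31-gene planted regulon
#'
#' A synthetic regulon whose ground-truth category composition matches the
#' published taxonomy of the OxyR regulon under constant H2O2 stress:
#' 11 sustained upregulated genes (7 pulsatile with peak/steady ratio 3,
#' 4 gradually responding with ratio 1.5), 8 sustained downregulated,
#' 7 transient downregulated, 2 transient upregulated and 3 unregulated
#' genes.  Genes named in the source taxonomy keep their names; the
#' remaining labels are synthetic.
#'
#' @return named list of 31 \code{\link{planted_template}}s.
#' @export
default_regulon_templates <- function() {
  pulsatile <- c("katG", "yaaA", "clpS", "hemH", "uxuA", "poxB", "yaiA")
  pulsatile_amp <- c(6.0, 5.4, 6.6, 5.7, 6.9, 6.3, 7.2)
  gradual <- c("grxA", "trxC", "fur", "ahpC")
  gradual_amp <- c(2.7, 2.4, 2.2, 3.0)
  tmpl <- list()
  for (i in seq_along(pulsatile)) {
    tmpl[[pulsatile[i]]] <- planted_template(
      pulsatile[i], "sustained_up", "pulsatile", peak_over_steady = 3,
      t_peak_mean = 25.7, t_peak_sd = 4.7, amplitude = pulsatile_amp[i],
      basal = 250 + 30 * i)
  }
  for (i in seq_along(gradual)) {
    tmpl[[gradual[i]]] <- planted_template(
      gradual[i], "sustained_up", "gradual", peak_over_steady = 1.5,
      t_peak_mean = 37.5, t_peak_sd = 7.8, amplitude = gradual_amp[i],
      basal = 280 + 40 * i)
  }
  for (i in 1:8) {
    nm <- if (i == 1) "fhuF" else sprintf("sdn%02d", i)
    tmpl[[nm]] <- planted_template(
      nm, "sustained_down", amplitude = 0.45 + 0.02 * i,
      basal = 300 + 25 * i)
  }
  for (i in 1:7) {
    nm <- sprintf("tdn%02d", i)
    tmpl[[nm]] <- planted_template(
      nm, "transient_down", amplitude = 0.3 + 0.03 * i,
      t_peak_mean = 25, t_peak_sd = 6, basal = 320 + 20 * i)
  }
  for (i in 1:2) {
    nm <- sprintf("tup%02d", i)
    tmpl[[nm]] <- planted_template(
      nm, "transient_up", amplitude = 1.8 + 0.4 * i,
      t_peak_mean = 25, t_peak_sd = 5, basal = 350 + 30 * i)
  }
  for (nm in c("hcp", "yfdL", "ybjN")) {
    tmpl[[nm]] <- planted_template(nm, "none", basal = 400)
  }
  tmpl
}
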