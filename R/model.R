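#' Growth rate as a function of intracellular H2O2
#'
#' Hill-type growth inhibition
#' \code{g(H) = g_max * K_g^n_g / (K_g^n_g + H^n_g)}: monotonically
#' non-increasing, \code{g(0) = g_max}, \code{g(K_g) = g_max / 2}, and
#' \code{g -> 0} as \code{H -> Inf}.
#'
#' @param h2o2_cell intracellular H2O2 concentration(s), uM (>= 0).
#' @param params an \code{\link{oxy_params}} object.
#' @return growth rate(s), min^-1.
#' @export
growth_rate <- function(h2o2_cell, params) {
  if (any(h2o2_cell < 0)) stop("h2o2_cell must be >= 0")
  kn <- params$K_g^params$n_g
  params$g_max * kn / (kn + h2o2_cell^params$n_g)
}

occupancy <- function(oxyr_ox, K_D) oxyr_ox / (oxyr_ox + K_D)

state_names <- function(genes) {
  c("OxyR_red", "GrxA", "KatG", "AhpC", "H2O2_cell", "n", "lnL",
    paste0("expr_", names(genes)))
}

#' Right-hand side of the oxidative stress response ODE system
#'
#' Time derivatives of the model state: reduced OxyR (oxidation by
#' intracellular H2O2 against GrxA-mediated reduction), the three regulon
#' proteins GrxA / KatG / AhpC (basal + OxyR-occupancy induction - growth
#' dilution), intracellular H2O2 (influx + endogenous production - the two
#' Michaelis-Menten scavenging terms), plasmid copy number, and one
#' expression variable per reporter gene.  Reporter production rates are
#' floored at zero so that downregulated genes can never produce at a
#' negative rate.
#'
#' @param state named numeric state vector (see \code{\link{basal_steady_state}}).
#' @param h2o2_external external H2O2 concentration, uM.
#' @param params an \code{\link{oxy_params}} object.
#' @param genes list of \code{\link{gene_spec}} objects.
#' @param growth_coupling if \code{FALSE}, dilution uses \code{g_max}
#'   regardless of intracellular H2O2 (constant-growth comparison).
#' @return named vector of time derivatives, per minute.
#' @export
oxy_derivatives <- function(state, h2o2_external, params, genes,
                            growth_coupling = TRUE) {
  if (h2o2_external < 0) stop("h2o2_external must be >= 0")
  genes <- as_gene_list(genes)
  p <- params
  oxy_red <- state[["OxyR_red"]]
  oxy_ox <- p$OxyR_total - oxy_red
  grxA <- state[["GrxA"]]; katG <- state[["KatG"]]; ahpC <- state[["AhpC"]]
  h <- state[["H2O2_cell"]]; n <- state[["n"]]
  g <- if (growth_coupling) growth_rate(max(h, 0), p) else p$g_max

  d_oxy_red <- -p$K_ox * oxy_red * h +
    p$K_red * grxA * oxy_ox / (oxy_ox + p$h_OxyR)
  d_grxA <- p$R_grxA_basal + p$Kind_GrxA * occupancy(oxy_ox, p$KD_GrxA) -
    g * grxA
  d_katG <- p$R_katG_basal + p$Kind_KatG * occupancy(oxy_ox, p$KD_KatG) -
    g * katG
  d_ahpC <- p$R_ahpC_basal + p$Kind_AhpC * occupancy(oxy_ox, p$KD_AhpC) -
    g * ahpC
  d_h <- p$R_influx * h2o2_external + p$R_H2O2_basal -
    p$K_AhpC * ahpC * h / (h + p$h_AhpC) -
    p$K_KatG * katG * h / (h + p$h_KatG)
  d_n <- p$R_n - g * n

  d_expr <- vapply(genes, function(gs) {
    ind <- gs$K_ind * occupancy(oxy_ox, gs$K_D)
    if (gs$on_plasmid) ind <- ind * n
    max(gs$R_basal + ind, 0) - g * state[[paste0("expr_", gs$name)]]
  }, numeric(1))

  # lnL accumulates integrated growth (log cell length); its increments
  # give the exact frame-averaged elongation rate of the simulated cell
  out <- c(d_oxy_red, d_grxA, d_katG, d_ahpC, d_h, d_n, g, d_expr)
  names(out) <- state_names(genes)
  out
}

ode_rhs <- function(t, state, parms) {
  h_ext <- h2o2_at(parms$protocol, t)
  list(oxy_derivatives(state, h_ext, parms$params, parms$genes,
                       parms$growth_coupling))
}

#' Basal steady state of the model under zero external H2O2
#'
#' Found by relaxation: a long integration under zero external H2O2
#' starting from an analytic first guess, verified by requiring all time
#' derivatives to fall below a tolerance.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @param genes list of \code{\link{gene_spec}}s (default: one constitutive
#'   control gene).
#' @param tol derivative tolerance (relative to state magnitude).
#' @param t_relax relaxation horizon, min.
#' @return named state vector.
#' @export
basal_steady_state <- function(params, genes = list(constitutive_gene(params)),
                               tol = 1e-6, t_relax = 2e5) {
  genes <- as_gene_list(genes)
  g0 <- params$g_max
  init <- c(
    OxyR_red = params$OxyR_total * 0.999,
    GrxA = max(params$R_grxA_basal / g0, 1e-4),
    KatG = params$R_katG_basal / g0,
    AhpC = params$R_ahpC_basal / g0,
    H2O2_cell = 1e-6,
    n = params$R_n / g0,
    lnL = 0,
    vapply(genes, function(gs) gs$R_basal / g0, numeric(1))
  )
  names(init) <- state_names(genes)
  parms <- list(params = params, protocol = protocol_none(t_pre = -1),
                genes = genes, growth_coupling = TRUE)
  sol <- deSolve::lsoda(init, times = c(0, t_relax / 2, t_relax), ode_rhs,
                        parms = parms, rtol = 1e-10, atol = 1e-12,
                        maxsteps = 1e5)
  if (attr(sol, "istate")[1] < 0) stop("basal relaxation failed to converge")
  st <- sol[nrow(sol), -1]
  names(st) <- state_names(genes)
  dv <- oxy_derivatives(st, 0, params, genes)
  dv <- dv[names(dv) != "lnL"]        # lnL grows forever by construction
  if (any(abs(dv) > tol * (1 + abs(st[names(dv)])))) {
    stop("basal steady state not reached within the relaxation horizon")
  }
  st[["lnL"]] <- 0
  st
}

#' Simulate the oxidative stress response under a treatment protocol
#'
#' Integrates the ODE system with a stiff-capable adaptive solver
#' (\code{deSolve::lsoda}, relative tolerance 1e-8, absolute 1e-10 by
#' default), segment by segment over the piecewise-constant protocol, and
#' samples the solution on a uniform output grid (default 3 min, the
#' imaging interval it mirrors).  The initial condition is the basal steady
#' state.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @param protocol an \code{\link{treatment_protocol}}.
#' @param genes list of \code{\link{gene_spec}}s.
#' @param t_start,t_end simulation window, min (treatment nominally at 0).
#' @param dt_out output sampling interval, min.
#' @param growth_coupling couple growth rate to intracellular H2O2.
#' @param rtol,atol solver tolerances.
#' @param init optional initial state (default: basal steady state).
#' @return An object of class \code{oxy_trajectory}: a data.frame with
#'   column \code{time} (min), one column per state variable, and
#'   \code{g_t}, the realized growth rate; attributes carry the inputs.
#' @examples
#' p <- oxy_params()
#' genes <- list(constitutive_gene(p), gene_spec("rep_down"))
#' tr <- simulate_regulon(p, protocol_step(100), genes,
#'                        t_start = -30, t_end = 60)
#' @export
simulate_regulon <- function(params, protocol, genes,
                             t_start = -120, t_end = 360, dt_out = 3,
                             growth_coupling = TRUE,
                             rtol = 1e-8, atol = 1e-10, init = NULL) {
  stopifnot(inherits(params, "oxy_params"), inherits(protocol, "oxy_protocol"))
  if (t_start >= t_end) stop("t_start must be < t_end")
  if (dt_out <= 0) stop("dt_out must be > 0")
  genes <- as_gene_list(genes)
  if (is.null(init)) init <- basal_steady_state(params, genes)
  if (!identical(names(init), state_names(genes))) {
    stop("init does not match the state layout for these genes")
  }

  grid <- seq(t_start, t_end, by = dt_out)
  seg <- protocol$segments
  breaks <- sort(unique(c(t_start, seg$start[seg$start > t_start &
                                               seg$start < t_end], t_end)))
  parms <- list(params = params, protocol = protocol, genes = genes,
                growth_coupling = growth_coupling)
  state <- init
  rows <- vector("list", length(breaks) - 1L)
  for (i in seq_len(length(breaks) - 1L)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1L]
    inner <- grid[grid > t0 & grid < t1]
    times <- unique(c(t0, inner, t1))
    sol <- deSolve::lsoda(state, times, ode_rhs, parms = parms,
                          rtol = rtol, atol = atol, maxsteps = 1e5)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("ODE integration failed in segment [%g, %g] min", t0, t1))
    }
    state <- sol[nrow(sol), -1]
    names(state) <- state_names(genes)
    keep <- sol[, 1] %in% grid
    rows[[i]] <- sol[keep, , drop = FALSE]
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out)[1] <- "time"
  out <- out[!duplicated(out$time), , drop = FALSE]
  rownames(out) <- NULL
  out$H2O2_cell <- pmax(out$H2O2_cell, 0)
  out$g_t <- if (growth_coupling) {
    growth_rate(out$H2O2_cell, params)
  } else {
    rep(params$g_max, nrow(out))
  }
  structure(out,
            class = c("oxy_trajectory", "data.frame"),
            params = params, protocol = protocol, genes = genes,
            growth_coupling = growth_coupling, dt_out = dt_out)
}

#' @export
print.oxy_trajectory <- function(x, ...) {
  genes <- attr(x, "genes")
  cat(sprintf(
    "<oxy_trajectory> %d samples, t in [%g, %g] min, protocol '%s', %d gene(s)\n",
    nrow(x), min(x$time), max(x$time), attr(x, "protocol")$label,
    length(genes)))
  cat("  genes:", paste(names(genes), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.oxy_trajectory <- function(x, vars = NULL, ...) {
  if (is.null(vars)) {
    vars <- grep("^expr_", names(x), value = TRUE)
    if (!length(vars)) vars <- "H2O2_cell"
  }
  old <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(old))
  for (v in vars) {
    graphics::plot(x$time, x[[v]], type = "l", xlab = "time (min)",
                   ylab = v, ...)
    graphics::abline(v = 0, lty = 2, col = "grey")
  }
  invisible(x)
}

#' Extract one gene's expression trace from a trajectory
#'
#' @param traj an \code{oxy_trajectory}.
#' @param gene gene name.
#' @return data.frame with \code{time}, \code{level}, \code{g_t}.
#' @export
gene_trace <- function(traj, gene) {
  col <- paste0("expr_", gene)
  if (!col %in% names(traj)) stop(sprintf("gene '%s' not in trajectory", gene))
  data.frame(time = traj$time, level = traj[[col]], g_t = traj$g_t,
             lnL = traj$lnL)
}

#' Dose-response of peak and steady-state expression
#'
#' Simulates a step treatment at each concentration and summarises the
#' reporter trace with the population peak / steady-state conventions
#' (90th percentile over the peak window; mean over the steady window),
#' both for the expression level and for the promoter activity
#' reconstructed from the trace.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @param gene a single \code{\link{gene_spec}}.
#' @param concentrations distinct external doses, uM (>= 0).
#' @param windows an \code{\link{analysis_windows}} object.
#' @param t_end simulation end, min.
#' @param ... passed to \code{\link{simulate_regulon}}.
#' @return data.frame with one row per concentration: \code{conc},
#'   \code{peak_level}, \code{steady_level}, \code{peak_activity},
#'   \code{steady_activity}, plus basal-normalised \code{peak_rel},
#'   \code{steady_rel}.
#' @export
dose_response <- function(params, gene, concentrations,
                          windows = analysis_windows(), t_end = 360, ...) {
  stopifnot(inherits(gene, "gene_spec"))
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (anyDuplicated(concentrations)) stop("concentrations must be distinct")
  rows <- lapply(concentrations, function(conc) {
    prot <- if (conc > 0) protocol_step(conc) else protocol_none()
    traj <- simulate_regulon(params, prot, list(gene),
                             t_start = -120, t_end = t_end, ...)
    m <- trajectory_metrics(traj, gene$name, windows)
    data.frame(conc = conc, peak_level = m$peak_level,
               steady_level = m$steady_level,
               peak_activity = m$peak_activity,
               steady_activity = m$steady_activity,
               peak_rel = m$peak_level / m$basal_level,
               steady_rel = m$steady_level / m$basal_level)
  })
  do.call(rbind, rows)
}

#' Simulate all positions of a growth trench
#'
#' Position k (k barrier cells between the cell and the open end) is
#' simulated with the external concentration attenuated by
#' \code{(1 - attenuation_per_cell)^k}, a static per-cell shielding factor.
#' Position 0 (the frontier) is the plain \code{\link{simulate_regulon}}
#' output.
#'
#' @param params an \code{\link{oxy_params}} object.
#' @param genes list of \code{\link{gene_spec}}s.
#' @param n_positions number of stacked cells (>= 1).
#' @param attenuation_per_cell fractional reduction of local H2O2 per
#'   shielding cell, in [0, 1).
#' @param protocol an \code{\link{treatment_protocol}}.
#' @param ... passed to \code{\link{simulate_regulon}}.
#' @return list of \code{oxy_trajectory}, one per position (barrier count
#'   0 .. n_positions - 1).
#' @export
trench_profile <- function(params, genes, n_positions,
                           attenuation_per_cell = 0.3, protocol, ...) {
  if (n_positions < 1) stop("n_positions must be >= 1")
  if (attenuation_per_cell < 0 || attenuation_per_cell >= 1) {
    stop("attenuation_per_cell must be in [0, 1)")
  }
  genes <- as_gene_list(genes)
  init <- basal_steady_state(params, genes)
  lapply(seq_len(n_positions) - 1L, function(k) {
    simulate_regulon(params,
                     scale_protocol(protocol, (1 - attenuation_per_cell)^k),
                     genes, init = init, ...)
  })
}

# Peak/steady metrics of a simulated trace, via the track-level estimators:
# the noiseless trajectory is treated as the population mean trace.
trajectory_metrics <- function(traj, gene, windows) {
  tr <- gene_trace(traj, gene)
  dt <- diff(tr$time[1:2])
  # measured elongation rate = log-difference of simulated cell length,
  # i.e. the exact average of g over each output interval
  elong <- c(NA, diff(tr$lnL)) / dt
  act <- promoter_activity_series(tr$level, elong, dt)
  lvl <- tr$level
  t <- tr$time
  in_w <- function(w) t >= w[1] & t <= w[2]
  basal <- t <= 0
  list(
    basal_level = mean(lvl[basal]),
    peak_level = quantile(lvl[in_w(windows$peak_level)], 0.9, type = 7,
                          names = FALSE),
    steady_level = mean(lvl[t >= windows$steady_level[1]]),
    basal_activity = mean(act[basal], na.rm = TRUE),
    peak_activity = quantile(act[in_w(windows$peak_activity)], 0.9,
                             type = 7, names = FALSE, na.rm = TRUE),
    steady_activity = mean(act[in_w(windows$steady_activity)], na.rm = TRUE)
  )
}
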