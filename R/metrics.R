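#' Instantaneous elongation rate from a cell length series
#'
#' Log-difference of cell length between consecutive frames,
#' \code{(log L_t - log L_(t-dt)) / dt}.  The first frame has no rate
#' (\code{NA}); frames immediately following a division (where the tracked
#' length drops to the daughter's) are also \code{NA}, since the rate is
#' undefined across the split.
#'
#' @param length cell length series, um (> 0).
#' @param dt frame interval, min.
#' @param new_cell optional logical series marking frames at which a new
#'   cell starts (division); defaults to none.
#' @return numeric series of rates, min^-1, same length as \code{length}.
#' @export
elongation_rate <- function(length, dt, new_cell = NULL) {
  if (length(length) < 2L) stop("need at least 2 frames")
  if (any(length <= 0)) stop("cell length must be > 0")
  r <- c(NA_real_, diff(log(length)) / dt)
  if (!is.null(new_cell)) r[which(new_cell)] <- NA_real_
  r
}

#' Instantaneous expression rate from an intensity series
#'
#' Difference of mean cell fluorescence intensity between consecutive
#' frames, \code{(I_t - I_(t-dt)) / dt}.
#'
#' @param intensity mean fluorescence series, a.u.
#' @param dt frame interval, min.
#' @return numeric series, a.u. min^-1 (first frame \code{NA}).
#' @export
expression_rate <- function(intensity, dt) {
  if (length(intensity) < 2L) stop("need at least 2 frames")
  c(NA_real_, diff(intensity) / dt)
}

promoter_activity_series <- function(intensity, elong, dt) {
  intensity * elong + expression_rate(intensity, dt)
}

#' Growth-corrected promoter activity
#'
#' The cell-averaged rate of change of total fluorescence,
#' \code{(1/A) d(I A)/dt = I (1/A)(dA/dt) + dI/dt}, with the relative area
#' growth \code{(1/A)(dA/dt)} given by the instantaneous elongation rate:
#' \code{activity_t = I_t * elongation_rate_t + expression_rate_t}.  This
#' separates transcriptional regulation from the passive concentration
#' changes caused by growth arrest (dilution).
#'
#' @inheritParams elongation_rate
#' @param intensity mean fluorescence series, a.u.
#' @return numeric series, a.u. min^-1 (NA where the elongation rate is
#'   undefined).
#' @export
promoter_activity <- function(intensity, length, dt, new_cell = NULL) {
  el <- elongation_rate(length, dt, new_cell)
  promoter_activity_series(intensity, el, dt)
}

# ---- population-level statistics on track datasets ----------------------

frontier_matrix <- function(ds, gene, channel = "gfp") {
  rec <- ds$records
  rec <- rec[rec$gene == gene & rec$barrier_count == 0L, , drop = FALSE]
  if (!nrow(rec)) stop(sprintf("no frontier records for gene '%s'", gene))
  col <- paste0("I_", channel)
  if (!col %in% names(rec)) stop(sprintf("no channel '%s' in dataset", channel))
  times <- sort(unique(rec$time))
  tr <- sort(unique(rec$trench_id))
  m <- matrix(NA_real_, length(tr), length(times),
              dimnames = list(tr, NULL))
  m[cbind(match(rec$trench_id, tr), match(rec$time, times))] <- rec[[col]]
  list(times = times, I = m, trenches = tr)
}

#' Population peak expression level
#'
#' The 90th percentile (linear-interpolation convention) of the mean
#' fluorescence intensity inside the peak window.  By default the
#' statistic is taken over time on the cross-cell mean-intensity trace of
#' the frontier cells (a robust maximum over the population time course);
#' \code{method = "pooled"} instead pools all per-cell values in the
#' window before taking the percentile.
#'
#' @param ds a \code{track_dataset}.
#' @param gene gene label.
#' @param windows an \code{\link{analysis_windows}} object.
#' @param channel fluorescence channel name.
#' @param normalize divide by the pre-treatment (t <= 0) frontier mean.
#' @param method \code{"mean_trace"} (default) or \code{"pooled"}.
#' @return scalar, a.u. (or fold-basal when normalized).
#' @export
population_peak <- function(ds, gene, windows = analysis_windows(),
                            channel = "gfp", normalize = FALSE,
                            method = c("mean_trace", "pooled")) {
  method <- match.arg(method)
  fm <- frontier_matrix(ds, gene, channel)
  sel <- in_window(fm$times, windows$peak_level)
  if (!any(sel)) stop("peak_level window contains no frames")
  x <- if (method == "mean_trace") {
    colMeans(fm$I[, sel, drop = FALSE], na.rm = TRUE)
  } else {
    as.vector(fm$I[, sel, drop = FALSE])
  }
  pk <- quantile(x, 0.9, type = 7, names = FALSE, na.rm = TRUE)
  if (normalize) pk <- pk / basal_level(ds, gene, channel)
  pk
}

#' Population steady-state expression level
#'
#' Mean frontier-cell intensity from the steady window start (default
#' 150 min post treatment) to the end of the data.
#'
#' @inheritParams population_peak
#' @return scalar, a.u. (or fold-basal when normalized).
#' @export
population_steady <- function(ds, gene, windows = analysis_windows(),
                              channel = "gfp", normalize = FALSE) {
  fm <- frontier_matrix(ds, gene, channel)
  sel <- fm$times >= windows$steady_level[1]
  if (!any(sel)) stop("steady_level window contains no frames")
  st <- mean(fm$I[, sel, drop = FALSE], na.rm = TRUE)
  if (normalize) st <- st / basal_level(ds, gene, channel)
  st
}

#' Pre-treatment basal expression level
#'
#' Mean frontier-cell intensity over t <= 0 (population basal).
#'
#' @inheritParams population_peak
#' @return scalar, a.u.
#' @export
basal_level <- function(ds, gene, channel = "gfp") {
  fm <- frontier_matrix(ds, gene, channel)
  sel <- fm$times <= 0
  if (!any(sel)) stop("no pre-treatment frames for the basal window")
  mean(fm$I[, sel, drop = FALSE], na.rm = TRUE)
}

# ---- single-cell statistics ---------------------------------------------

#' Single-cell time to peak expression
#'
#' Time post treatment (0 < t <= horizon, default 100 min) at which the
#' cell's fluorescence is maximal; ties broken to the earliest frame.
#'
#' With \code{interpolate = TRUE} the peak position is refined to
#' sub-frame resolution by fitting a parabola through the discrete
#' maximum and its two neighbours (standard sub-sample peak
#' localization); at the window boundary the frame time is returned
#' unchanged.
#'
#' @param time time series, min.
#' @param intensity fluorescence series, a.u.
#' @param windows an \code{\link{analysis_windows}} object.
#' @param interpolate refine the peak time by parabolic interpolation.
#' @return time of the maximum, min.
#' @export
cell_time_to_peak <- function(time, intensity,
                              windows = analysis_windows(),
                              interpolate = FALSE) {
  sel <- time > 0 & time <= windows$time_to_peak_horizon
  if (!any(sel)) stop("time-to-peak window contains no frames")
  t <- time[sel]; x <- intensity[sel]
  i <- which.max(x)
  if (!interpolate || i == 1L || i == length(x)) return(t[i])
  dt <- t[i + 1L] - t[i]
  den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (den >= 0) return(t[i])
  shift <- 0.5 * (x[i - 1L] - x[i + 1L]) / den
  t[i] + max(min(shift, 1), -1) * dt
}

#' Single-cell peak expression
#'
#' Mean fluorescence over the single-cell peak window (default 18-90 min
#' post treatment) minus the cell's own pre-treatment basal mean.
#'
#' @inheritParams cell_time_to_peak
#' @return baseline-subtracted peak expression, a.u.
#' @export
cell_peak <- function(time, intensity, windows = analysis_windows()) {
  sel <- in_window(time, windows$single_cell_peak)
  basal <- time <= 0
  if (!any(sel)) stop("single_cell_peak window contains no frames")
  if (!any(basal)) stop("no pre-treatment frames for the basal window")
  mean(intensity[sel]) - mean(intensity[basal])
}

#' Coefficient of variation
#'
#' Standard deviation (sample, n-1 denominator) divided by the mean.
#'
#' @param values numeric vector (>= 2 values, nonzero mean).
#' @return CV, dimensionless.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  sd(values) / m
}

#' Gene-to-gene expression variability over time
#'
#' Per frame, the coefficient of variation across the per-gene frontier
#' mean intensities, each normalized to its own pre-treatment basal mean.
#' In a stress-responsive regulon this variability is low before
#' treatment, maximal during the transient expression peak and
#' intermediate at steady state.
#'
#' @param ds a \code{track_dataset} containing several genes.
#' @param channel fluorescence channel name.
#' @return data.frame with \code{time} and \code{cv}.
#' @export
gene_to_gene_cv <- function(ds, channel = "gfp") {
  genes <- sort(unique(ds$records$gene))
  if (length(genes) < 2L) stop("need at least 2 genes")
  traces <- lapply(genes, function(g) {
    fm <- frontier_matrix(ds, g, channel)
    mt <- colMeans(fm$I, na.rm = TRUE)
    mt / mean(mt[fm$times <= 0])
  })
  times <- frontier_matrix(ds, genes[1], channel)$times
  m <- do.call(rbind, traces)
  data.frame(time = times,
             cv = apply(m, 2, function(v) sd(v) / mean(v)))
}

#' Relative expression along the trench (spatial profile)
#'
#' Within each trench at each frame in the window, the intensity of every
#' cell with at least one barrier cell is divided by the intensity of the
#' outermost (frontier, barrier count 0) cell; ratios are then averaged
#' over frames and across trenches.  Trenches without a frontier record at
#' a frame are skipped with a warning.
#'
#' @param ds a \code{track_dataset}.
#' @param gene gene label.
#' @param window numeric length-2 time window, min.
#' @param channel fluorescence channel name.
#' @return data.frame with \code{barrier_count} and mean \code{ratio}
#'   (barrier count 0 is identically 1).
#' @export
relative_spatial_profile <- function(ds, gene, window, channel = "gfp") {
  rec <- ds$records
  col <- paste0("I_", channel)
  rec <- rec[rec$gene == gene & in_window(rec$time, window), , drop = FALSE]
  if (!nrow(rec)) stop("window contains no records for this gene")
  key <- paste(rec$trench_id, rec$time)
  front <- rec$barrier_count == 0L
  ref <- setNames(rec[[col]][front], key[front])
  miss <- !(key %in% names(ref))
  if (any(miss)) {
    warning(sprintf("%d trench-frames without a frontier cell skipped",
                    length(unique(key[miss]))))
    rec <- rec[!miss, , drop = FALSE]
    key <- key[!miss]
  }
  ratio <- rec[[col]] / ref[key]
  # per-trench mean ratio per barrier count, then across trenches
  per_trench <- tapply(ratio,
                       list(rec$barrier_count, rec$trench_id),
                       mean, na.rm = TRUE)
  data.frame(barrier_count = as.integer(rownames(per_trench)),
             ratio = rowMeans(per_trench, na.rm = TRUE),
             row.names = NULL)
}

#' Temporal cross-correlation of steady-state expression fluctuations
#'
#' Both traces are detrended by subtracting a centered moving average
#' (default 30 min) to isolate fluctuations from the slow induction trend,
#' then correlated at lags up to \code{max_lag} frames.  Given matrices
#' (one row per trench/mother cell), correlations are computed per trench
#' and averaged.
#'
#' @param trace_a,trace_b numeric vectors, or matrices with one row per
#'   trench and one column per frame (steady-state segment).
#' @param max_lag maximum lag, frames.
#' @param dt frame interval, min.
#' @param detrend_window moving-average window, min (0 disables).
#' @return data.frame with \code{lag_min} and mean \code{corr} in [-1, 1].
#' @export
cross_correlation <- function(trace_a, trace_b, max_lag = 10, dt = 3,
                              detrend_window = 30) {
  if (is.vector(trace_a)) trace_a <- matrix(trace_a, nrow = 1)
  if (is.vector(trace_b)) trace_b <- matrix(trace_b, nrow = 1)
  stopifnot(identical(dim(trace_a), dim(trace_b)))
  nf <- ncol(trace_a)
  if (nf < 2 * max_lag + 2) stop("segment too short for the requested max_lag")
  detrend <- function(x) {
    if (detrend_window <= 0) return(x - mean(x))
    k <- max(1L, round(detrend_window / dt)) * 2L + 1L
    trend <- stats::filter(x, rep(1 / k, k), sides = 2)
    pad <- is.na(trend)
    trend[pad] <- mean(x)
    as.numeric(x - trend)
  }
  lags <- -max_lag:max_lag
  cors <- sapply(seq_len(nrow(trace_a)), function(i) {
    a <- detrend(trace_a[i, ]); b <- detrend(trace_b[i, ])
    vapply(lags, function(l) {
      if (l >= 0) {
        ai <- a[seq_len(nf - l)]; bi <- b[seq_len(nf - l) + l]
      } else {
        ai <- a[seq_len(nf + l) - l]; bi <- b[seq_len(nf + l)]
      }
      if (sd(ai) == 0 || sd(bi) == 0) return(NA_real_)
      stats::cor(ai, bi)
    }, numeric(1))
  })
  data.frame(lag_min = lags * dt, corr = rowMeans(cors, na.rm = TRUE))
}

#' Population promoter-activity peak/steady ratio
#'
#' Reconstructs per-trace promoter activity for the frontier cells,
#' averages it across traces per frame, and summarises the mean activity
#' trace with the peak convention (90th percentile over the peak-activity
#' window) against the mean over the steady-activity window.  This is the
#' growth-corrected analogue of the expression-level peak/steady ratio;
#' for deterministic model traces, whose level ratio is compressed by
#' dilution, the class contrast between high- and low-K_D promoters lives
#' here.
#'
#' @param ds a \code{track_dataset}.
#' @param gene gene label.
#' @param windows an \code{\link{analysis_windows}} object.
#' @param channel fluorescence channel name.
#' @return scalar peak/steady activity ratio.
#' @export
population_activity_ratio <- function(ds, gene,
                                      windows = analysis_windows(),
                                      channel = "gfp") {
  tr <- activity_trace(ds, gene, channel)
  pk <- quantile(tr$activity[in_window(tr$time, windows$peak_activity)],
                 0.9, type = 7, names = FALSE, na.rm = TRUE)
  st <- mean(tr$activity[in_window(tr$time, windows$steady_activity)],
             na.rm = TRUE)
  pk / st
}

# population mean promoter-activity trace of the frontier cells
activity_trace <- function(ds, gene, channel = "gfp") {
  rec <- ds$records
  col <- paste0("I_", channel)
  dt <- ds$manifest$layout$frame_interval
  rec <- rec[rec$barrier_count == 0L & rec$gene == gene, , drop = FALSE]
  rec <- rec[order(rec$trench_id, rec$time), , drop = FALSE]
  times <- sort(unique(rec$time))
  tr <- unique(rec$trench_id)
  shape <- function(v) {
    m <- matrix(NA_real_, length(tr), length(times))
    m[cbind(match(rec$trench_id, tr), match(rec$time, times))] <- v
    m
  }
  I <- shape(rec[[col]]); L <- shape(rec$length_um)
  newc <- shape(as.numeric(!duplicated(paste(rec$trench_id,
                                             rec$cell_id)))) > 0
  dL <- t(apply(log(L), 1, function(x) c(NA, diff(x)))) / dt
  dL[newc] <- NA
  dI <- t(apply(I, 1, function(x) c(NA, diff(x)))) / dt
  act <- I * dL + dI
  data.frame(time = times, activity = colMeans(act, na.rm = TRUE))
}

# ---- per-trace activity window means (classifier input) -----------------

#' Per-trace promoter-activity window means
#'
#' For every gene and every tracked frontier trace, the mean reconstructed
#' promoter activity in the basal (t <= 0), peak and steady activity
#' windows.  These per-cell means are the units of the windowed rank tests
#' in \code{\link{classify_regulon}}.
#'
#' @param ds a \code{track_dataset}.
#' @param windows an \code{\link{analysis_windows}} object.
#' @param channel fluorescence channel name.
#' @return data.frame with columns \code{gene}, \code{trench_id},
#'   \code{basal}, \code{peak}, \code{steady}.
#' @export
activity_window_means <- function(ds, windows = analysis_windows(),
                                  channel = "gfp") {
  rec <- ds$records
  col <- paste0("I_", channel)
  dt <- ds$manifest$layout$frame_interval
  rec <- rec[rec$barrier_count == 0L, , drop = FALSE]
  rec <- rec[order(rec$gene, rec$trench_id, rec$time), , drop = FALSE]
  out <- list()
  for (g in unique(rec$gene)) {
    sub <- rec[rec$gene == g, , drop = FALSE]
    times <- sort(unique(sub$time))
    tr <- unique(sub$trench_id)
    shape <- function(v) {
      m <- matrix(NA_real_, length(tr), length(times))
      m[cbind(match(sub$trench_id, tr), match(sub$time, times))] <- v
      m
    }
    I <- shape(sub[[col]]); L <- shape(sub$length_um)
    newc <- shape(as.numeric(!duplicated(paste(sub$trench_id, sub$cell_id)))) > 0
    dL <- t(apply(log(L), 1, function(x) c(NA, diff(x)))) / dt
    dL[newc] <- NA
    dI <- t(apply(I, 1, function(x) c(NA, diff(x)))) / dt
    act <- I * dL + dI
    wmean <- function(w_sel) rowMeans(act[, w_sel, drop = FALSE], na.rm = TRUE)
    out[[g]] <- data.frame(
      gene = g, trench_id = tr,
      basal = wmean(times <= 0),
      peak = wmean(in_window(times, windows$peak_activity)),
      steady = wmean(in_window(times, windows$steady_activity))
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
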