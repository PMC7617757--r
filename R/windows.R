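#' Analysis time windows
#'
#' All statistics are computed in fixed windows relative to the treatment
#' start (t = 0 min, which itself belongs to the pre-treatment basal
#' window).  Defaults: population peak level 12-90 min (90th percentile),
#' steady-state level from 150 min on (mean), promoter-activity peak
#' window 9-60 min and steady window 120-180 min (the rank-test windows),
#' single-cell peak window 18-90 min, and a 100-min horizon for
#' single-cell time-to-peak.  A window (a, b) includes frames with
#' a <= t <= b on the sampling grid.
#'
#' @param peak_level numeric length-2, min.
#' @param steady_level_start start of the steady-state level window, min
#'   (the window runs to the end of the data).
#' @param peak_activity,steady_activity numeric length-2, min.
#' @param single_cell_peak numeric length-2, min.
#' @param time_to_peak_horizon single-cell time-to-peak horizon, min.
#' @return Object of class \code{analysis_windows}.
#' @export
analysis_windows <- function(peak_level = c(12, 90),
                             steady_level_start = 150,
                             peak_activity = c(9, 60),
                             steady_activity = c(120, 180),
                             single_cell_peak = c(18, 90),
                             time_to_peak_horizon = 100) {
  w <- list(peak_level = peak_level,
            steady_level = c(steady_level_start, Inf),
            peak_activity = peak_activity,
            steady_activity = steady_activity,
            single_cell_peak = single_cell_peak,
            time_to_peak_horizon = time_to_peak_horizon)
  for (nm in c("peak_level", "peak_activity", "steady_activity",
               "single_cell_peak")) {
    if (length(w[[nm]]) != 2L || w[[nm]][1] >= w[[nm]][2]) {
      stop(sprintf("window '%s' must satisfy start < end", nm))
    }
  }
  if (time_to_peak_horizon <= 0) stop("time_to_peak_horizon must be > 0")
  structure(w, class = "analysis_windows")
}

#' @export
print.analysis_windows <- function(x, ...) {
  cat("<analysis_windows> (min, relative to treatment start)\n")
  cat(sprintf("  level : peak %g-%g | steady >= %g\n",
              x$peak_level[1], x$peak_level[2], x$steady_level[1]))
  cat(sprintf("  activity: peak %g-%g | steady %g-%g | basal t <= 0\n",
              x$peak_activity[1], x$peak_activity[2],
              x$steady_activity[1], x$steady_activity[2]))
  cat(sprintf("  single cell: peak %g-%g | time-to-peak <= %g\n",
              x$single_cell_peak[1], x$single_cell_peak[2],
              x$time_to_peak_horizon))
  invisible(x)
}

in_window <- function(t, w) t >= w[1] & t <= w[2]
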