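#' Piecewise-constant external H2O2 treatment protocols
#'
#' A treatment protocol is an ordered set of segments, each holding the
#' external H2O2 concentration constant from its start time until the next
#' segment begins.  The first segment must start at or before t = 0 (the
#' nominal treatment start used by all analysis windows).
#'
#' @param segments data.frame with columns \code{start} (min, strictly
#'   increasing) and \code{conc} (uM, >= 0).
#' @param label protocol label, one of \code{"step"}, \code{"graded"},
#'   \code{"none"} or a free label.
#' @return Object of class \code{oxy_protocol}.
#' @seealso \code{\link{protocol_step}}, \code{\link{protocol_graded}},
#'   \code{\link{protocol_none}}
#' @export
treatment_protocol <- function(segments, label = "custom") {
  stopifnot(is.data.frame(segments),
            all(c("start", "conc") %in% names(segments)),
            nrow(segments) >= 1L)
  if (is.unsorted(segments$start, strictly = TRUE)) {
    stop("segment start times must be strictly increasing")
  }
  if (any(segments$conc < 0)) stop("H2O2 concentrations must be >= 0")
  if (segments$start[1] > 0) stop("first segment must start at or before t = 0")
  structure(list(segments = segments[, c("start", "conc")], label = label),
            class = "oxy_protocol")
}

#' @rdname treatment_protocol
#' @param conc external H2O2 concentration, uM.
#' @param t_on treatment start time, min.
#' @param t_pre start of the modelled pre-treatment baseline, min (< t_on).
#' @export
protocol_step <- function(conc = 100, t_on = 0, t_pre = -1e6) {
  treatment_protocol(
    data.frame(start = c(t_pre, t_on), conc = c(0, conc)),
    label = "step"
  )
}

#' @rdname treatment_protocol
#' @param concs increasing doses, uM (graded default 25 -> 50 -> 100).
#' @param times switch times for each dose, min.
#' @export
protocol_graded <- function(concs = c(25, 50, 100), times = c(0, 60, 120),
                            t_pre = -1e6) {
  stopifnot(length(concs) == length(times))
  treatment_protocol(
    data.frame(start = c(t_pre, times), conc = c(0, concs)),
    label = "graded"
  )
}

#' @rdname treatment_protocol
#' @export
protocol_none <- function(t_pre = -1e6) {
  treatment_protocol(data.frame(start = t_pre, conc = 0), label = "none")
}

#' External H2O2 concentration at given times
#'
#' @param protocol an \code{oxy_protocol}.
#' @param t vector of times, min.
#' @return numeric vector of concentrations, uM.
#' @export
h2o2_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "oxy_protocol"))
  seg <- protocol$segments
  idx <- findInterval(t, seg$start)
  out <- rep(0, length(t))
  out[idx >= 1] <- seg$conc[idx[idx >= 1]]
  out
}

#' @export
print.oxy_protocol <- function(x, ...) {
  cat(sprintf("<oxy_protocol> '%s' with %d segment(s)\n",
              x$label, nrow(x$segments)))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

#' Scale a protocol's concentrations
#'
#' Used by the trench spatial model, where position k behind the open end
#' sees the external dose attenuated by (1 - attenuation)^k.
#'
#' @param protocol an \code{oxy_protocol}.
#' @param factor multiplicative factor >= 0.
#' @return scaled \code{oxy_protocol}.
#' @export
scale_protocol <- function(protocol, factor) {
  stopifnot(factor >= 0)
  protocol$segments$conc <- protocol$segments$conc * factor
  protocol
}
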