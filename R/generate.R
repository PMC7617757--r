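#' Mother-machine channel layout
#'
#' Geometry and timing of the emulated experiment: trenches of stacked
#' cells imaged at a fixed frame interval, with a pre-treatment baseline
#' followed by constant treatment.
#'
#' @param n_trenches number of growth trenches (>= 1).
#' @param cells_per_trench stacked cells per trench (>= 1); barrier counts
#'   run 0 (frontier, open end) .. cells_per_trench - 1 (mother cell).
#' @param frame_interval imaging interval, min.
#' @param t_pre pre-treatment baseline duration, min.
#' @param t_post treatment duration, min.
#' @return Object of class \code{channel_layout}.
#' @export
channel_layout <- function(n_trenches = 20, cells_per_trench = 7,
                           frame_interval = 3, t_pre = 120, t_post = 360) {
  stopifnot(n_trenches >= 1, cells_per_trench >= 1, frame_interval > 0,
            t_pre >= frame_interval, t_post >= frame_interval)
  structure(list(n_trenches = as.integer(n_trenches),
                 cells_per_trench = as.integer(cells_per_trench),
                 frame_interval = frame_interval,
                 t_pre = t_pre, t_post = t_post),
            class = "channel_layout")
}

layout_times <- function(layout) {
  seq(-layout$t_pre, layout$t_post, by = layout$frame_interval)
}

# exact per-interval mean of the shared planted growth-arrest profile,
# computed from a fine-grid integral (the onset discontinuity at t = 0
# makes frame-endpoint averages biased)
arrest_g_interval <- function(times) {
  tf <- seq(min(times), max(times), by = 0.1)
  gf <- growth_arrest_profile(tf)
  cum <- c(0, cumsum((gf[-1] + gf[-length(gf)]) / 2) * diff(tf))
  cum_at <- approx(tf, cum, times)$y
  c(0, diff(cum_at) / diff(times))
}

#' Measurement and fluctuation noise model for synthetic tracks
#'
#' Fluorescence is modelled as
#' \code{I = level * cell_factor * OU(t) * meas(t)}: a persistent
#' per-lineage lognormal scale factor (reporter copy-number / expression
#' capacity differences between lineages), a slow multiplicative
#' Ornstein-Uhlenbeck fluctuation, and frame-wise lognormal measurement
#' noise.  All multiplicative components have mean 1.  Cell length carries
#' its own small measurement noise.
#'
#' @param meas_cv frame-wise measurement noise CV.
#' @param ou_cv stationary CV of the slow expression fluctuations.
#' @param ou_tau correlation time of the fluctuations, min.
#' @param shared_fraction fraction of the OU fluctuation variance shared
#'   between two reporter channels in the same cell, in [0, 1].
#' @param cell_cv CV of the persistent per-lineage scale factor.
#' @param length_cv measurement noise CV of cell length.
#' @param div_cv lognormal noise on the division length threshold.
#' @param seed integer RNG seed used by the generator.
#' @return Object of class \code{noise_model}.
#' @export
noise_model <- function(meas_cv = 0.05, ou_cv = 0.15, ou_tau = 30,
                        shared_fraction = 0, cell_cv = 0.4,
                        length_cv = 0.01, div_cv = 0.05, seed = 1L) {
  stopifnot(meas_cv >= 0, ou_cv >= 0, ou_tau > 0, cell_cv >= 0,
            length_cv >= 0, div_cv >= 0,
            shared_fraction >= 0, shared_fraction <= 1)
  structure(list(meas_cv = meas_cv, ou_cv = ou_cv, ou_tau = ou_tau,
                 shared_fraction = shared_fraction, cell_cv = cell_cv,
                 length_cv = length_cv, div_cv = div_cv,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Noise-free noise model (ground-truth recovery runs)
#' @param seed integer RNG seed.
#' @return \code{\link{noise_model}} with every component zero.
#' @export
noise_off <- function(seed = 1L) {
  noise_model(meas_cv = 0, ou_cv = 0, ou_tau = 30, shared_fraction = 0,
              cell_cv = 0, length_cv = 0, div_cv = 0, seed = seed)
}

lognorm_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

# matrix of mean-1 multiplicative OU fluctuations: one row per trace
ou_matrix <- function(n_traces, n_frames, dt, ou_cv, ou_tau,
                      z_shared = NULL, shared_fraction = 0) {
  if (ou_cv <= 0) {
    return(list(f = matrix(1, n_traces, n_frames), z = NULL))
  }
  rho <- exp(-dt / ou_tau)
  z <- matrix(0, n_traces, n_frames)
  z[, 1] <- rnorm(n_traces)
  for (j in 2:n_frames) {
    z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n_traces)
  }
  zz <- if (!is.null(z_shared) && shared_fraction > 0) {
    sqrt(shared_fraction) * z_shared + sqrt(1 - shared_fraction) * z
  } else z
  sdl <- sqrt(log(1 + ou_cv^2))
  list(f = exp(sdl * zz - sdl^2 / 2), z = z)
}

# stochastic exponential elongation with threshold division
# g_interval[j]: exact mean growth rate over (t_{j-1}, t_j]; returns true
# length matrix and generation index matrix
grow_lengths <- function(n_traces, times, g_interval, div_cv) {
  nf <- length(times)
  dt <- diff(times)
  L <- matrix(0, n_traces, nf)
  gen <- matrix(0L, n_traces, nf)
  birth <- lognorm_factor(n_traces, 0.05) * 1.0          # birth length, um
  thresh <- 2 * birth * lognorm_factor(n_traces, div_cv)
  L[, 1] <- birth * exp(runif(n_traces) * log(2))        # random cycle phase
  g_now <- rep(0L, n_traces)
  gen[, 1] <- g_now
  for (j in 2:nf) {
    Lj <- L[, j - 1] * exp(g_interval[j] * dt[j - 1])
    div <- Lj >= thresh
    if (any(div)) {
      Lj[div] <- Lj[div] / 2                             # symmetric split
      birth[div] <- Lj[div]
      thresh[div] <- 2 * birth[div] * lognorm_factor(sum(div), div_cv)
      g_now[div] <- g_now[div] + 1L
    }
    L[, j] <- Lj
    gen[, j] <- g_now
  }
  list(L = L, gen = gen)
}

assemble_records <- function(gene, trench_ids, barrier_count, times,
                             I_true, g_interval, noise, channels,
                             ou_shared = NULL) {
  n_traces <- nrow(I_true[[1]])
  nf <- length(times)
  dt <- diff(times[1:2])
  gl <- grow_lengths(n_traces, times, g_interval, noise$div_cv)
  L_meas <- gl$L * matrix(lognorm_factor(n_traces * nf, noise$length_cv),
                          n_traces, nf)
  cols <- list()
  for (ch in channels) {
    cfac <- lognorm_factor(n_traces, noise$cell_cv)
    ou <- ou_matrix(n_traces, nf, dt, noise$ou_cv, noise$ou_tau,
                    z_shared = ou_shared, shared_fraction =
                      if (is.null(ou_shared)) 0 else noise$shared_fraction)
    meas <- matrix(lognorm_factor(n_traces * nf, noise$meas_cv),
                   n_traces, nf)
    cols[[paste0("I_", ch)]] <- as.vector(t(I_true[[ch]] * cfac * ou$f * meas))
  }
  base <- data.frame(
    trench_id = rep(trench_ids, each = nf),
    barrier_count = rep(barrier_count, each = nf),
    cell_id = paste0("tr", rep(trench_ids, each = nf), "_p",
                     rep(barrier_count, each = nf), "_g",
                     as.vector(t(gl$gen))),
    lineage_id = paste0("tr", rep(trench_ids, each = nf), "_p",
                        rep(barrier_count, each = nf)),
    gene = gene,
    time = rep(times, n_traces),
    length_um = as.vector(t(L_meas)),
    area_um2 = as.vector(t(L_meas)) * 1.0,
    stringsAsFactors = FALSE
  )
  cbind(base, as.data.frame(cols))
}

#' Generate a synthetic mother-machine track dataset
#'
#' In \code{"planted"} mode each gene follows a
#' \code{\link{planted_template}} (with per-cell peak-time variation for
#' peaked categories); in \code{"mechanistic"} mode gene expression and
#' growth come from \code{\link{trench_profile}} simulations of the ODE
#' model, with the external dose attenuated by
#' \code{(1 - attenuation)^barrier_count}.  Noise is applied per
#' \code{\link{noise_model}}; the run is bit-reproducible given the seed.
#'
#' @param mode \code{"planted"} or \code{"mechanistic"}.
#' @param layout a \code{\link{channel_layout}}.
#' @param templates named list of \code{planted_template}s (planted mode).
#' @param noise a \code{\link{noise_model}}.
#' @param params,protocol,genes ODE model inputs (mechanistic mode).
#' @param attenuation per-cell H2O2 attenuation fraction (mechanistic).
#' @param dose external dose scaling applied to planted templates, uM.
#' @return Object of class \code{track_dataset}: list with \code{records}
#'   (one row per cell per frame) and \code{manifest} (generation
#'   parameters and ground-truth labels; never in the data table).
#' @export
generate_tracks <- function(mode = c("planted", "mechanistic"),
                            layout = channel_layout(),
                            templates = NULL, noise = noise_model(),
                            params = NULL, protocol = NULL, genes = NULL,
                            attenuation = 0.3, dose = 100) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "channel_layout"),
            inherits(noise, "noise_model"))
  set.seed(noise$seed)
  times <- layout_times(layout)
  positions <- seq_len(layout$cells_per_trench) - 1L
  recs <- list()

  if (mode == "planted") {
    if (is.null(templates)) stop("planted mode needs templates")
    if (inherits(templates, "planted_template")) templates <- list(templates)
    names(templates) <- vapply(templates, `[[`, character(1), "gene")
    truth <- lapply(templates, function(tm) {
      tm[c("gene", "category", "dynamics", "peak_over_steady",
           "t_peak_mean", "t_peak_sd", "amplitude", "basal")]
    })
    for (tm in templates) {
      tm_d <- scale_template_dose(tm, dose)
      calib <- calibrate_template(tm_d, t_pre = layout$t_pre,
                                  t_post = layout$t_post)
      peaked <- tm_d$category == "sustained_up"
      for (k in positions) {
        n_tr <- layout$n_trenches
        lvl <- matrix(0, n_tr, length(times))
        if (peaked && tm_d$t_peak_sd > 0) {
          tpk <- rnorm(n_tr, tm_d$t_peak_mean, tm_d$t_peak_sd)
          tpk <- pmax(tpk, 6)
          for (i in seq_len(n_tr)) {
            lvl[i, ] <- planted_trace(tm_d, times, t_peak = tpk[i],
                                      calib = calib)$level
          }
        } else {
          tr1 <- planted_trace(tm_d, times, calib = calib)$level
          lvl <- matrix(tr1, n_tr, length(times), byrow = TRUE)
        }
        recs[[paste(tm$gene, k)]] <- assemble_records(
          tm$gene, seq_len(n_tr), k, times,
          list(gfp = lvl),
          g_interval = arrest_g_interval(times),
          noise = noise, channels = "gfp")
      }
    }
    manifest <- list(mode = mode, layout = unclass(layout),
                     noise = unclass(noise), dose = dose,
                     ground_truth = truth, channels = "gfp")
  } else {
    if (is.null(params) || is.null(protocol) || is.null(genes)) {
      stop("mechanistic mode needs params, protocol and genes")
    }
    genes <- as_gene_list(genes)
    trajs <- trench_profile(params, genes, layout$cells_per_trench,
                            attenuation, protocol,
                            t_start = -layout$t_pre, t_end = layout$t_post,
                            dt_out = layout$frame_interval)
    for (gs in genes) {
      for (k in positions) {
        tr <- gene_trace(trajs[[k + 1L]], gs$name)
        lvl <- matrix(tr$level, layout$n_trenches, length(times),
                      byrow = TRUE)
        recs[[paste(gs$name, k)]] <- assemble_records(
          gs$name, seq_len(layout$n_trenches), k, times,
          list(gfp = lvl),
          g_interval = c(0, diff(tr$lnL)) / layout$frame_interval,
          noise = noise, channels = "gfp")
      }
    }
    manifest <- list(mode = mode, layout = unclass(layout),
                     noise = unclass(noise),
                     attenuation = attenuation,
                     protocol = list(label = protocol$label,
                                     segments = protocol$segments),
                     genes = lapply(genes, unclass),
                     params = unclass(params), channels = "gfp")
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  structure(list(records = records, manifest = manifest),
            class = "track_dataset")
}

#' Generate a dual-reporter track dataset
#'
#' One strain carrying two reporters in the same cells (channels
#' \code{yfp} and \code{cfp}), whose slow expression fluctuations share a
#' fraction \code{noise$shared_fraction} of their variance — the planted
#' analogue of co-regulated reporters read out in two colours.
#'
#' @param template_yfp,template_cfp \code{\link{planted_template}}s.
#' @param layout a \code{\link{channel_layout}}.
#' @param noise a \code{\link{noise_model}}.
#' @return \code{track_dataset} with channels \code{I_yfp}, \code{I_cfp};
#'   the gene column holds "yfp_name/cfp_name".
#' @export
generate_dual_tracks <- function(template_yfp, template_cfp,
                                 layout = channel_layout(),
                                 noise = noise_model()) {
  set.seed(noise$seed)
  times <- layout_times(layout)
  nf <- length(times)
  n_tr <- layout$n_trenches
  lvl <- lapply(list(yfp = template_yfp, cfp = template_cfp), function(tm) {
    calib <- calibrate_template(tm, t_pre = layout$t_pre,
                                t_post = layout$t_post)
    matrix(planted_trace(tm, times, calib = calib)$level, n_tr, nf,
           byrow = TRUE)
  })
  dt <- layout$frame_interval
  rho_z <- ou_matrix(n_tr, nf, dt, max(noise$ou_cv, 1e-9), noise$ou_tau)$z
  recs <- assemble_records(
    paste(template_yfp$gene, template_cfp$gene, sep = "/"),
    seq_len(n_tr), 0L, times, lvl,
    g_interval = arrest_g_interval(times),
    noise = noise, channels = c("yfp", "cfp"), ou_shared = rho_z)
  manifest <- list(mode = "planted_dual", layout = unclass(layout),
                   noise = unclass(noise),
                   ground_truth = list(yfp = unclass(template_yfp),
                                       cfp = unclass(template_cfp)),
                   channels = c("yfp", "cfp"))
  structure(list(records = recs, manifest = manifest),
            class = "track_dataset")
}

#' @export
print.track_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf(
    "<track_dataset> %d records | %d gene(s) | %d trench(es) | t %g..%g min (%s mode)\n",
    nrow(r), length(unique(r$gene)), length(unique(r$trench_id)),
    min(r$time), max(r$time), x$manifest$mode))
  invisible(x)
}

required_track_columns <- function() {
  c("trench_id", "barrier_count", "cell_id", "lineage_id", "gene",
    "time", "length_um", "area_um2")
}

#' Write / read a track dataset
#'
#' Tracks are stored as a plain CSV (documented column order:
#' trench_id, barrier_count, cell_id, lineage_id, gene, time, length_um,
#' area_um2, then one \code{I_<channel>} column per channel); the manifest
#' goes to a JSON sidecar \code{<path>_manifest.json}.  Numeric columns
#' are written with full (17 significant digit) precision so that
#' write -> read -> write is byte-identical.
#'
#' @param ds a \code{track_dataset}.
#' @param path CSV file path.
#' @return \code{write_tracks}: the path, invisibly.  \code{read_tracks}:
#'   the \code{track_dataset}.
#' @export
write_tracks <- function(ds, path) {
  stopifnot(inherits(ds, "track_dataset"))
  rec <- ds$records
  num <- vapply(rec, is.numeric, logical(1))
  out <- rec
  out[num] <- lapply(rec[num], function(x) sprintf("%.17g", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  manifest_path <- paste0(tools::file_path_sans_ext(path),
                          "_manifest.json")
  jsonlite::write_json(ds$manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  nfield <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nfield != nfield[1])
  if (length(bad)) {
    stop(sprintf("ragged CSV: line %d has %d fields, expected %d",
                 bad[1], nfield[bad[1]], nfield[1]))
  }
  rec <- tryCatch(
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop(sprintf("malformed tracks CSV '%s': %s",
                                     path, conditionMessage(e))))
  missing_cols <- setdiff(required_track_columns(), names(rec))
  if (length(missing_cols)) {
    stop(sprintf("tracks CSV is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!any(grepl("^I_", names(rec)))) {
    stop("tracks CSV is missing required column(s): I_<channel>")
  }
  manifest_path <- paste0(tools::file_path_sans_ext(path),
                          "_manifest.json")
  manifest <- if (file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else list()
  structure(list(records = rec, manifest = manifest),
            class = "track_dataset")
}
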