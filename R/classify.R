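#' Windowed Mann-Whitney test of a promoter-activity change
#'
#' Two-sided rank-sum comparison of per-cell promoter-activity window
#' means against the same cells' pre-treatment basal means.  The exact
#' null distribution is used for small tie-free samples (both n <= 8);
#' otherwise the normal approximation with tie correction.  The direction
#' is the sign of the window-median shift, forced to \code{"none"} when
#' p > alpha.
#'
#' @param activity_basal per-cell basal window means.
#' @param activity_window per-cell treatment window means.
#' @param alpha significance level.
#' @return list with \code{direction} ("up"/"down"/"none"), \code{p}, and
#'   the median \code{shift}.
#' @export
window_test <- function(activity_basal, activity_window, alpha = 0.05) {
  activity_basal <- activity_basal[!is.na(activity_basal)]
  activity_window <- activity_window[!is.na(activity_window)]
  if (!length(activity_basal) || !length(activity_window)) {
    stop("empty sample in window_test")
  }
  ties <- anyDuplicated(c(activity_basal, activity_window)) > 0
  exact <- !ties && max(length(activity_basal), length(activity_window)) <= 8
  p <- suppressWarnings(
    wilcox.test(activity_window, activity_basal, alternative = "two.sided",
                exact = exact, correct = TRUE)$p.value)
  shift <- median(activity_window) - median(activity_basal)
  direction <- if (p > alpha || shift == 0) "none" else
    if (shift > 0) "up" else "down"
  list(direction = direction, p = p, shift = shift)
}

#' Combine peak- and steady-window calls into a regulation category
#'
#' The five-category taxonomy: significant in both windows with the same
#' sign -> sustained up/down; significant at the peak only -> transient
#' up/down; neither -> none.  The overall direction is always taken from
#' the peak window (the change immediately after treatment); genes whose
#' steady-window call disagrees in sign (e.g. down at the peak, up at
#' steady) keep the peak direction with sustained persistence and are
#' flagged discordant rather than silently coerced.
#'
#' @param peak_call,steady_call results of \code{\link{window_test}}.
#' @return list with \code{direction}, \code{persistence},
#'   \code{category}, \code{discordant}.
#' @export
assign_category <- function(peak_call, steady_call) {
  pd <- peak_call$direction; sd_ <- steady_call$direction
  discordant <- pd != "none" && sd_ != "none" && pd != sd_
  direction <- pd
  persistence <- if (pd == "none") {
    "none"
  } else if (sd_ == "none") {
    "transient"
  } else {
    "sustained"
  }
  category <- if (direction == "none") "none" else
    paste(persistence, direction, sep = "_")
  list(direction = direction, persistence = persistence,
       category = category, discordant = discordant)
}

#' Classify every gene of a track dataset into regulation categories
#'
#' Computes per-trace promoter-activity window means
#' (\code{\link{activity_window_means}}), runs the peak- and
#' steady-window rank tests for each gene and assigns the five-way
#' category.
#'
#' @param ds a \code{track_dataset}.
#' @param windows an \code{\link{analysis_windows}} object.
#' @param alpha significance level.
#' @param p_adjust multiple-testing correction across genes
#'   (\code{"none"} by default; \code{"BH"} available).
#' @param channel fluorescence channel.
#' @return Object of class \code{regulon_report}: a data.frame with one
#'   row per gene (direction, persistence, category, p-values, flags) and
#'   an attribute \code{counts} with the per-category totals.
#' @export
classify_regulon <- function(ds, windows = analysis_windows(),
                             alpha = 0.05, p_adjust = c("none", "BH"),
                             channel = "gfp") {
  p_adjust <- match.arg(p_adjust)
  aw <- activity_window_means(ds, windows, channel)
  genes <- unique(aw$gene)
  res <- lapply(genes, function(g) {
    sub <- aw[aw$gene == g, ]
    pk <- window_test(sub$basal, sub$peak, alpha)
    st <- window_test(sub$basal, sub$steady, alpha)
    data.frame(gene = g, p_peak = pk$p, p_steady = st$p,
               shift_peak = pk$shift, shift_steady = st$shift,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (p_adjust == "BH") {
    res$p_peak <- p.adjust(res$p_peak, "BH")
    res$p_steady <- p.adjust(res$p_steady, "BH")
  }
  calls <- lapply(seq_len(nrow(res)), function(i) {
    mk <- function(p, shift) {
      list(direction = if (p > alpha || shift == 0) "none" else
        if (shift > 0) "up" else "down", p = p, shift = shift)
    }
    assign_category(mk(res$p_peak[i], res$shift_peak[i]),
                    mk(res$p_steady[i], res$shift_steady[i]))
  })
  res$direction <- vapply(calls, `[[`, character(1), "direction")
  res$persistence <- vapply(calls, `[[`, character(1), "persistence")
  res$category <- vapply(calls, `[[`, character(1), "category")
  res$discordant <- vapply(calls, `[[`, logical(1), "discordant")
  counts <- table(factor(res$category,
                         levels = c("sustained_up", "transient_up",
                                    "sustained_down", "transient_down",
                                    "none")))
  structure(res, class = c("regulon_report", "data.frame"),
            counts = counts, alpha = alpha)
}

#' @export
print.regulon_report <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat(sprintf("<regulon_report> %d genes at alpha = %g\n", nrow(x),
              attr(x, "alpha")))
  for (nm in names(cnt)) cat(sprintf("  %-15s %d\n", nm, cnt[[nm]]))
  if (any(x$discordant)) {
    cat("  discordant:", paste(x$gene[x$discordant], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.regulon_report <- function(object, ...) {
  list(counts = attr(object, "counts"), alpha = attr(object, "alpha"),
       n_genes = nrow(object), discordant = object$gene[object$discordant])
}

#' Peak vs steady-state linear regression
#'
#' Ordinary least squares of per-gene-per-dose peak expression against
#' steady-state expression (both relative to basal).  The fitted slope is
#' the peak/steady ratio of the class; the intercept is retained for
#' diagnostics.
#'
#' @param steady,peak numeric vectors (>= 3 points).
#' @return list with \code{slope}, \code{intercept}, \code{r_squared}.
#' @export
peak_vs_steady_regression <- function(steady, peak) {
  stopifnot(length(steady) == length(peak))
  if (length(steady) < 3) stop("need at least 3 points")
  if (sd(steady) == 0) stop("degenerate regression: steady values constant")
  fit <- lm(peak ~ steady)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((peak - mean(peak))^2)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = 1 - ss_res / ss_tot)
}

#' Split upregulated genes into pulsatile and gradually responding
#'
#' Genes whose peak/steady ratio (regression slope) is at or above the
#' threshold are pulsatile; below, gradually responding.  The default
#' threshold 2.12 is the geometric midpoint of the two published class
#' ratios (~3 and ~1.5).
#'
#' @param ratios named numeric vector of per-gene peak/steady ratios.
#' @param threshold classification threshold.
#' @return data.frame with \code{gene}, \code{ratio}, \code{dynamics}.
#' @export
split_pulsatile_gradual <- function(ratios, threshold = 2.12) {
  stopifnot(all(is.finite(ratios)))
  data.frame(gene = if (is.null(names(ratios)))
    as.character(seq_along(ratios)) else names(ratios),
    ratio = unname(ratios),
    dynamics = ifelse(ratios >= threshold, "pulsatile", "gradual"),
    stringsAsFactors = FALSE)
}

#' Dose sensitivity of peak and steady expression
#'
#' OLS slopes of basal-normalised expression level versus external dose,
#' separately for the peak and steady windows.  Pulsatile (high K_D)
#' genes show steeper peak slopes than gradually responding genes.
#'
#' @param doses external doses, uM (>= 3 distinct values).
#' @param peak_rel,steady_rel basal-normalised levels per dose.
#' @return list with \code{peak_slope}, \code{steady_slope}.
#' @export
dose_sensitivity <- function(doses, peak_rel, steady_rel) {
  if (length(unique(doses)) < 3) stop("need at least 3 doses")
  list(peak_slope = unname(coef(lm(peak_rel ~ doses))[2]),
       steady_slope = unname(coef(lm(steady_rel ~ doses))[2]))
}
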