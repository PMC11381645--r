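#' Score a CGM record on the three-dimensional model
#'
#' Runs the full scoring pipeline for one patient: harmonize to the
#' 15-minute grid, drop days below the availability threshold, compute
#' daily LBGI/HBGI/GVP, normalize to 0-100 dimension scores, enumerate
#' sliding multi-day windows, and aggregate each window with the weighted
#' hypoglycemia rule. Every window also carries its AGP metrics so the
#' result can feed calibration directly.
#'
#' @param x a `cgm_series` (raw samples) or a `cgm_days` object (already
#'   gridded).
#' @param params a [normalization_params()] object.
#' @param cohort `"adult"` or `"pediatric"`; defaults to the cohort tag
#'   carried by `x`.
#' @param window_length scoring window in calendar days (default 14).
#' @param hypo_subset_fraction see [aggregate_period()] (default 0.5).
#' @param min_day_availability daily availability threshold (default
#'   0.70).
#' @param min_period_availability window availability threshold (default
#'   0.70).
#' @param clamp sensor reporting range passed to [resample_to_grid()].
#' @return object of class `cgm_score` with components `days`
#'   (`cgm_days`), `daily` (per-day indices and scores), `windows`
#'   (per-window scores, segment and AGP metrics), `daily_by_window`
#'   (list of per-window daily score tables), and the settings used.
#' @examples
#' s <- simulate_patient(sim_config(days_per_patient = 20, seed = 7), 1)
#' sc <- score_cgm(s)
#' sc
#' head(sc$windows)
#' @export
score_cgm <- function(x, params = normalization_params(), cohort = NULL,
                      window_length = 14L, hypo_subset_fraction = 0.5,
                      min_day_availability = 0.70,
                      min_period_availability = 0.70,
                      clamp = SENSOR_RANGE) {
  days <- if (inherits(x, "cgm_series")) resample_to_grid(x, clamp) else x
  stopifnot(inherits(days, "cgm_days"))
  if (is.null(cohort)) cohort <- days$cohort
  kept <- filter_days(days, min_day_availability)
  if (length(kept) == 0)
    stop("no day passes the availability filter", call. = FALSE)
  idx <- daily_indices(kept)
  daily <- cbind(idx, normalize_daily(idx[, c("lbgi", "hbgi", "gvp")],
                                      params, cohort))
  windows <- enumerate_windows(kept, window_length,
                               min_period_availability)
  day_index <- attr(windows, "day_index")
  per_window <- vector("list", nrow(windows))
  daily_by_window <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    member <- day_index[[i]]
    dsc <- daily[member, c("hypo", "hyper", "var"), drop = FALSE]
    daily_by_window[[i]] <- dsc
    per_window[[i]] <- cbind(aggregate_period(dsc, hypo_subset_fraction),
                             agp_metrics(kept[member]))
  }
  win <- if (nrow(windows))
    cbind(patient_id = days$patient_id,
          windows[, c("start_date", "end_date", "availability")],
          do.call(rbind, per_window))
  else
    data.frame()
  rownames(win) <- NULL
  structure(list(days = kept, daily = daily, windows = win,
                 daily_by_window = daily_by_window, params = params,
                 cohort = cohort, window_length = window_length,
                 hypo_subset_fraction = hypo_subset_fraction,
                 call = match.call()),
            class = "cgm_score")
}

#' @export
print.cgm_score <- function(x, ...) {
  cat(sprintf("Three-dimensional CGM score: patient %s (%s)\n",
              x$days$patient_id, x$cohort))
  cat(sprintf("  %d scored day(s), %d window(s) of %d days\n",
              nrow(x$daily), nrow(x$windows), x$window_length))
  if (nrow(x$windows)) {
    latest <- x$windows[nrow(x$windows), ]
    cat(sprintf(paste0("  latest window %s .. %s: hypo %.1f, hyper %.1f,",
                       " var %.1f\n  single score %.1f (%s, lowest: %s)\n"),
                format(latest$start_date), format(latest$end_date),
                latest$hypo, latest$hyper, latest$var, latest$single,
                latest$segment, latest$lowest_dimension))
  }
  invisible(x)
}

#' @export
summary.cgm_score <- function(object, ...) {
  w <- object$windows
  out <- list(
    patient_id = object$days$patient_id, cohort = object$cohort,
    n_days = nrow(object$daily), n_windows = nrow(w),
    daily = if (nrow(object$daily))
      summary(object$daily[, c("lbgi", "hbgi", "gvp", "hypo", "hyper",
                               "var")]),
    single = if (nrow(w)) summary(w$single),
    segments = if (nrow(w))
      table(factor(w$segment, levels = names(segment_palette()))))
  class(out) <- "summary.cgm_score"
  out
}

#' @export
print.summary.cgm_score <- function(x, ...) {
  cat(sprintf("Patient %s (%s): %d scored days, %d windows\n",
              x$patient_id, x$cohort, x$n_days, x$n_windows))
  if (!is.null(x$single)) {
    cat("Single score over windows:\n"); print(x$single)
    cat("Segment counts:\n"); print(x$segments)
  }
  invisible(x)
}

#' @export
as.data.frame.cgm_score <- function(x, ...) x$windows

#' Plot method for scored CGM records
#'
#' `type = "single"` draws the single-score trajectory over window start
#' dates on the segment-colored background; `type = "daily"` draws the
#' three daily dimension scores.
#'
#' @param x a `cgm_score` object.
#' @param type `"single"` or `"daily"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.cgm_score <- function(x, type = c("single", "daily"), ...) {
  type <- match.arg(type)
  pal <- segment_palette()
  if (type == "single") {
    if (!nrow(x$windows)) stop("no windows to plot", call. = FALSE)
    plot(x$windows$start_date, x$windows$single, type = "n",
         ylim = c(0, 100), xlab = "window start",
         ylab = "single score", ...)
    b <- c(0, 20, 40, 60, 80, 100)
    usr <- graphics::par("usr")
    for (i in seq_len(5))
      graphics::rect(usr[1], b[i], usr[2], b[i + 1],
                     col = grDevices::adjustcolor(pal[i], alpha.f = 0.25),
                     border = NA)
    graphics::lines(x$windows$start_date, x$windows$single, lwd = 2)
    graphics::points(x$windows$start_date, x$windows$single, pch = 19)
  } else {
    d <- x$daily
    plot(d$date, d$hypo, type = "l", ylim = c(0, 100), col = "#D7301F",
         xlab = "date", ylab = "daily dimension score", ...)
    graphics::lines(d$date, d$hyper, col = "#FC8D59")
    graphics::lines(d$date, d$var, col = "#2B8CBE")
    graphics::legend("bottomleft",
                     legend = c("hypoglycemia", "hyperglycemia",
                                "variability"),
                     col = c("#D7301F", "#FC8D59", "#2B8CBE"), lty = 1,
                     bty = "n")
  }
  invisible(x)
}
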