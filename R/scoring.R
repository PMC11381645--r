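#' Min-max normalization parameters for the three score dimensions
#'
#' Each raw daily index is mapped to a 0-100 score by
#' `100 * (1 - (x - min) / (max - min))`, clamped to `[0, 100]`: the best
#' attainable index value scores 100 and the cohort's 98th-percentile
#' (most alarming) value scores 0. Defaults are the published calibration:
#' LBGI 0-8, HBGI 0-32 (adult) / 0-30 (pediatric), GVP 20-67. The GVP
#' minimum of 20% reflects the best level observed in people without
#' diabetes. Refit from a cohort with [fit_normalization()].
#'
#' @param lbgi_min,lbgi_max,hbgi_min,gvp_min,gvp_max per-dimension
#'   normalization bounds.
#' @param hbgi_max_adult,hbgi_max_pediatric cohort-specific HBGI maxima
#'   (the pediatric treatment target is stricter).
#' @return list of class `cgm_norm_params`.
#' @export
normalization_params <- function(lbgi_min = 0, lbgi_max = 8,
                                 hbgi_min = 0, hbgi_max_adult = 32,
                                 hbgi_max_pediatric = 30,
                                 gvp_min = 20, gvp_max = 67) {
  p <- list(lbgi_min = lbgi_min, lbgi_max = lbgi_max,
            hbgi_min = hbgi_min, hbgi_max_adult = hbgi_max_adult,
            hbgi_max_pediatric = hbgi_max_pediatric,
            gvp_min = gvp_min, gvp_max = gvp_max)
  if (!(lbgi_min < lbgi_max && gvp_min < gvp_max &&
        (is.na(hbgi_max_adult) || hbgi_min < hbgi_max_adult) &&
        (is.na(hbgi_max_pediatric) || hbgi_min < hbgi_max_pediatric)))
    stop("each normalization minimum must be below its maximum",
         call. = FALSE)
  structure(p, class = "cgm_norm_params")
}

#' @export
print.cgm_norm_params <- function(x, ...) {
  cat("Normalization parameters (index value scoring 100 .. 0):\n")
  cat(sprintf("  LBGI %g .. %g\n", x$lbgi_min, x$lbgi_max))
  cat(sprintf("  HBGI %g .. %g (adult) / %g (pediatric)\n",
              x$hbgi_min, x$hbgi_max_adult, x$hbgi_max_pediatric))
  cat(sprintf("  GVP  %g .. %g\n", x$gvp_min, x$gvp_max))
  invisible(x)
}

minmax_score <- function(x, min, max) {
  pmin(pmax(100 * (1 - (x - min) / (max - min)), 0), 100)
}

#' Normalize daily indices to 0-100 dimension scores
#'
#' @param indices data frame from [daily_indices()] (columns `lbgi`,
#'   `hbgi`, `gvp`, optionally `date`).
#' @param params a [normalization_params()] object.
#' @param cohort `"adult"` or `"pediatric"`; selects the HBGI maximum.
#' @return data frame with columns `date` (if present), `hypo`, `hyper`,
#'   `var`, each in `[0, 100]` (100 = best, 0 = most alarming).
#' @examples
#' normalize_daily(data.frame(lbgi = 0, hbgi = 0, gvp = 20),
#'                 cohort = "adult")  # all 100
#' @export
normalize_daily <- function(indices, params = normalization_params(),
                            cohort = c("adult", "pediatric")) {
  cohort <- match.arg(cohort)
  stopifnot(inherits(params, "cgm_norm_params"))
  hbgi_max <- if (cohort == "adult") params$hbgi_max_adult
              else params$hbgi_max_pediatric
  if (is.na(hbgi_max))
    stop("no HBGI maximum available for cohort '", cohort, "'",
         call. = FALSE)
  out <- data.frame(
    hypo  = minmax_score(indices$lbgi, params$lbgi_min, params$lbgi_max),
    hyper = minmax_score(indices$hbgi, params$hbgi_min, hbgi_max),
    var   = minmax_score(indices$gvp, params$gvp_min, params$gvp_max))
  if (!is.null(indices$date)) out <- cbind(date = indices$date, out)
  out
}

#' Segment palette on the single score
#'
#' Five color-coded segments of width 20, each closed on its lower bound:
#' dark red `[0,20)`, red `[20,40)`, orange `[40,60)`, yellow `[60,80)`
#' and green `[80,100]`. Green is calibrated to indicate likely
#' fulfillment of all consensus CGM treatment targets.
#'
#' @return named character vector of display colors, names in ascending
#'   segment order.
#' @export
segment_palette <- function() {
  c(dark_red = "#67000D", red = "#D7301F", orange = "#FC8D59",
    yellow = "#FEE08B", green = "#1A9850")
}

#' Classify a single score into its color segment
#'
#' @param single numeric vector of single scores in `[0, 100]`.
#' @return factor with levels `dark_red < red < orange < yellow < green`.
#' @examples
#' classify_segment(c(80, 79, 15))  # green, yellow, dark_red
#' @export
classify_segment <- function(single) {
  if (any(single < 0 | single > 100, na.rm = TRUE))
    stop("single score outside [0, 100]", call. = FALSE)
  cut(single, breaks = c(0, 20, 40, 60, 80, 100),
      labels = names(segment_palette()), right = FALSE,
      include.lowest = TRUE, ordered_result = TRUE)
}

#' Aggregate daily scores over a scoring window
#'
#' The hypoglycemia dimension of a period is the mean of its
#' `ceiling(hypo_subset_fraction * n_days)` lowest daily hypoglycemia
#' scores (default: the lowest half, i.e. 7 of 14 days), so that a
#' minority of alarming hypoglycemic days is not averaged away. The
#' hyperglycemia and variability dimensions are plain means over all
#' days. The single score is the minimum of the three period dimensions;
#' ties on the lowest dimension resolve in the order hypoglycemia,
#' hyperglycemia, variability.
#'
#' @param daily data frame of daily scores (columns `hypo`, `hyper`,
#'   `var`), rows with `NA` in any dimension are dropped.
#' @param hypo_subset_fraction fraction of lowest-scoring days
#'   representing the hypoglycemia dimension, in `(0, 1]`; default 0.5.
#' @return one-row data frame: `hypo`, `hyper`, `var`, `single`,
#'   `lowest_dimension`, `segment`, `n_days`.
#' @examples
#' d <- data.frame(hypo = c(rep(20, 7), rep(100, 7)),
#'                 hyper = 70, var = 90)
#' aggregate_period(d)  # hypo 20, single 20
#' @export
aggregate_period <- function(daily, hypo_subset_fraction = 0.5) {
  stopifnot(hypo_subset_fraction > 0, hypo_subset_fraction <= 1)
  ok <- stats::complete.cases(daily[, c("hypo", "hyper", "var")])
  daily <- daily[ok, , drop = FALSE]
  n <- nrow(daily)
  if (n == 0)
    stop("cannot aggregate an empty set of daily scores", call. = FALSE)
  k <- ceiling(hypo_subset_fraction * n)
  hypo <- mean(sort(daily$hypo)[seq_len(k)])
  hyper <- mean(daily$hyper)
  v <- mean(daily$var)
  dims <- c(hypoglycemia = hypo, hyperglycemia = hyper, variability = v)
  single <- min(dims)
  lowest <- names(dims)[which.min(dims)]  # first minimum = tie-break order
  data.frame(hypo = hypo, hyper = hyper, var = v, single = single,
             lowest_dimension = lowest,
             segment = as.character(classify_segment(single)),
             n_days = n)
}

#' Sweep the hypoglycemia subset size against AGP correlations
#'
#' Recomputes the period single score for every candidate number of
#' lowest-scoring days `k` representing the hypoglycemia dimension and
#' reports the Spearman correlation of the single score with each AGP
#' metric across windows. The published calibration balances the severe
#' excursion metrics (TSAR vs TSBR) at `k = 7` of 14 days.
#'
#' @param daily_by_window list of daily-score data frames, one per window
#'   (as consumed by [aggregate_period()]).
#' @param agp data frame of per-window AGP metrics, rows aligned with
#'   `daily_by_window`; must contain the columns in `metrics`.
#' @param k_range integer vector of candidate subset sizes (default
#'   `1:14`).
#' @param metrics AGP metric columns to correlate against.
#' @return data frame with one row per `k` and one correlation column per
#'   metric; constant score vectors yield `NA`.
#' @export
hypo_subset_sweep <- function(daily_by_window, agp, k_range = 1:14,
                              metrics = c("tar", "tsar", "tbr", "tsbr",
                                          "cv")) {
  stopifnot(length(daily_by_window) == nrow(agp),
            length(daily_by_window) >= 10,
            all(metrics %in% names(agp)))
  out <- lapply(k_range, function(k) {
    single <- vapply(daily_by_window, function(d) {
      d <- d[stats::complete.cases(d[, c("hypo", "hyper", "var")]), ,
             drop = FALSE]
      kk <- min(k, nrow(d))
      min(mean(sort(d$hypo)[seq_len(kk)]), mean(d$hyper), mean(d$var))
    }, numeric(1))
    r <- vapply(metrics, function(m) {
      if (stats::sd(single) == 0 || stats::sd(agp[[m]]) == 0)
        return(NA_real_)
      stats::cor(single, agp[[m]], method = "spearman")
    }, numeric(1))
    c(k = k, r)
  })
  as.data.frame(do.call(rbind, out))
}
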