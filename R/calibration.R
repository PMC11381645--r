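#' Consensus CGM treatment targets
#'
#' The international consensus targets for a 14-day CGM period: time in
#' range above 70%, time below range under 4% (under 1% below 3.0
#' mmol/L), time above range under 25% (under 5% above 13.9 mmol/L) and a
#' coefficient of variation of at most 36%. Boundary comparisons are
#' inclusive in the direction of fulfillment.
#'
#' @param tir_min,tbr_max,tsbr_max,tar_max,tsar_max,cv_max thresholds in
#'   percent.
#' @return list of class `cgm_targets`.
#' @export
target_set <- function(tir_min = 70, tbr_max = 4, tsbr_max = 1,
                       tar_max = 25, tsar_max = 5, cv_max = 36) {
  structure(list(tir_min = tir_min, tbr_max = tbr_max,
                 tsbr_max = tsbr_max, tar_max = tar_max,
                 tsar_max = tsar_max, cv_max = cv_max),
            class = "cgm_targets")
}

#' Do AGP metrics fulfill all treatment targets?
#'
#' @param metrics data frame of AGP metrics (one or more rows, columns as
#'   in [agp_metrics()]).
#' @param targets a [target_set()].
#' @return logical vector, `TRUE` where every target is met.
#' @examples
#' targets_fulfilled(agp_metrics(rep(110, 96)))  # TRUE
#' @export
targets_fulfilled <- function(metrics, targets = target_set()) {
  stopifnot(inherits(targets, "cgm_targets"))
  metrics$tir >= targets$tir_min & metrics$tbr <= targets$tbr_max &
    metrics$tsbr <= targets$tsbr_max & metrics$tar <= targets$tar_max &
    metrics$tsar <= targets$tsar_max & metrics$cv <= targets$cv_max
}

#' Fit normalization maxima from a cohort of daily indices
#'
#' The per-dimension maxima (score 0, the most alarming end) are the
#' empirical upper percentile of the cohort's daily index distributions
#' (default the 98th percentile); the HBGI maximum is fitted separately
#' per cohort. Minima stay at the fixed convention 0 / 0 / 20.
#'
#' @param indices data frame with columns `lbgi`, `hbgi`, `gvp` and
#'   `cohort` (`"adult"` / `"pediatric"`).
#' @param percentile upper percentile used as the maximum, default 0.98.
#' @return a [normalization_params()] object; a missing cohort stratum
#'   leaves its HBGI maximum `NA` with a warning.
#' @export
fit_normalization <- function(indices, percentile = 0.98) {
  stopifnot(percentile > 0, percentile <= 1)
  ok <- stats::complete.cases(indices[, c("lbgi", "hbgi", "gvp")])
  indices <- indices[ok, , drop = FALSE]
  if (nrow(indices) == 0) stop("empty cohort", call. = FALSE)
  if (nrow(indices) < 100)
    warning("fewer than 100 days; fitted percentiles will be unstable",
            call. = FALSE)
  q <- function(x) if (length(x)) unname(stats::quantile(x, percentile))
                   else NA_real_
  hb_ad <- q(indices$hbgi[indices$cohort == "adult"])
  hb_pe <- q(indices$hbgi[indices$cohort == "pediatric"])
  if (is.na(hb_ad) || is.na(hb_pe))
    warning("cohort stratum missing; its HBGI maximum is NA",
            call. = FALSE)
  normalization_params(lbgi_max = q(indices$lbgi),
                       hbgi_max_adult = hb_ad,
                       hbgi_max_pediatric = hb_pe,
                       gvp_max = q(indices$gvp))
}

#' Empirical ROC curve and cutoff at a false-positive-rate bound
#'
#' Builds the empirical ROC of the single score as a classifier of
#' target fulfillment (predicted positive when `score >= t`), computes
#' the area under it by the trapezoidal rule, and selects the smallest
#' observed score whose false positive rate does not exceed the bound
#' (default 2.5%).
#'
#' @param scores numeric vector of single scores.
#' @param labels logical vector: `TRUE` where the window truly fulfills
#'   all targets.
#' @param fpr_bound acceptable false positive rate, default 0.025.
#' @return list of class `cgm_roc`: `auc`, `threshold`,
#'   `fpr_at_threshold`, `tpr_at_threshold`, `sensitivity`,
#'   `specificity`, `accuracy`, and the full `curve` (threshold, fpr,
#'   tpr).
#' @examples
#' roc_cutoff(c(90, 85, 70, 60), c(TRUE, TRUE, FALSE, FALSE))
#' @export
roc_cutoff <- function(scores, labels, fpr_bound = 0.025) {
  stopifnot(length(scores) == length(labels), is.logical(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both fulfilled and unfulfilled windows are required for a ROC",
         call. = FALSE)
  th <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(th, function(t) sum(scores >= t & labels) / n_pos,
                numeric(1))
  fpr <- vapply(th, function(t) sum(scores >= t & !labels) / n_neg,
                numeric(1))
  curve <- data.frame(threshold = c(Inf, th), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  adm <- th[fpr <= fpr_bound]
  if (length(adm) == 0)
    stop("no observed score satisfies the FPR bound", call. = FALSE)
  t0 <- min(adm)
  pred <- scores >= t0
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  structure(list(auc = auc, threshold = t0,
                 fpr_at_threshold = fp / n_neg,
                 tpr_at_threshold = tp / n_pos,
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(scores),
                 fpr_bound = fpr_bound, n_pos = n_pos, n_neg = n_neg,
                 curve = curve),
            class = "cgm_roc")
}

#' @export
print.cgm_roc <- function(x, ...) {
  cat(sprintf("ROC of single score vs target fulfillment (n+ %d, n- %d)\n",
              x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f; cutoff %.1f at FPR bound %.1f%%\n", x$auc,
              x$threshold, 100 * x$fpr_bound))
  cat(sprintf("  sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$accuracy))
  invisible(x)
}

#' Spearman correlations between score dimensions and AGP metrics
#'
#' @param windows data frame with score columns (`hypo`, `hyper`, `var`,
#'   `single`) and AGP metric columns.
#' @param score_cols,metric_cols columns to correlate.
#' @return list of class `cgm_cor`: matrices `r` and `p` (scores x
#'   metrics). Constant columns give `NA` entries. p-values use the
#'   t approximation for `n >= 30` and the exact distribution below.
#' @export
correlation_matrix <- function(windows,
                               score_cols = c("hypo", "hyper", "var",
                                              "single"),
                               metric_cols = c("tir", "tar", "tsar",
                                               "tbr", "tsbr", "cv",
                                               "gmi", "mean_glucose")) {
  stopifnot(nrow(windows) >= 10,
            all(c(score_cols, metric_cols) %in% names(windows)))
  n <- nrow(windows)
  r <- p <- matrix(NA_real_, length(score_cols), length(metric_cols),
                   dimnames = list(score_cols, metric_cols))
  for (s in score_cols) for (m in metric_cols) {
    x <- windows[[s]]; y <- windows[[m]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = n < 30))
    r[s, m] <- unname(ct$estimate)
    p[s, m] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n), class = "cgm_cor")
}

#' @export
print.cgm_cor <- function(x, digits = 2, ...) {
  cat(sprintf("Spearman correlations over %d windows:\n", x$n))
  print(round(x$r, digits))
  invisible(x)
}

#' Polynomial models of AGP metrics on score
#'
#' Ordinary least-squares polynomial (default second degree) of each AGP
#' metric on its score dimension, used to tabulate the AGP metric values
#' expected at each score level and segment.
#'
#' @param windows per-window data frame with score and metric columns.
#' @param pairs two-column character matrix or data frame of
#'   (score, metric) pairs to fit; defaults to each dimension against
#'   its relevant metrics plus the single score against all.
#' @param degree polynomial degree, default 2.
#' @return data frame of class `cgm_polyfit`: one row per pair with
#'   coefficients `c0..c<degree>` and `r2`; fitted `lm` objects in
#'   `attr(, "fits")`.
#' @export
polynomial_models <- function(windows, pairs = NULL, degree = 2) {
  if (is.null(pairs)) {
    pairs <- rbind(
      data.frame(score = "hypo", metric = c("tbr", "tsbr")),
      data.frame(score = "hyper", metric = c("tar", "tsar", "gmi",
                                             "mean_glucose")),
      data.frame(score = "var", metric = "cv"),
      data.frame(score = "single",
                 metric = c("tir", "tar", "tsar", "tbr", "tsbr", "cv",
                            "gmi")))
  }
  stopifnot(nrow(windows) >= degree + 2)
  fits <- vector("list", nrow(pairs))
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$score[i]; m <- pairs$metric[i]
    df <- data.frame(x = windows[[s]], y = windows[[m]])
    fit <- stats::lm(y ~ poly(x, degree, raw = TRUE), data = df)
    if (any(is.na(stats::coef(fit))))
      stop("rank-deficient polynomial fit for ", s, " vs ", m,
           call. = FALSE)
    co <- unname(stats::coef(fit))
    row <- data.frame(score = s, metric = m, r2 = summary(fit)$r.squared)
    for (d in 0:degree) row[[paste0("c", d)]] <- co[d + 1]
    rows[[i]] <- row
    fits[[i]] <- fit
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  class(out) <- c("cgm_polyfit", "data.frame")
  out
}

#' Expected AGP metrics per score segment
#'
#' Evaluates fitted single-score polynomial models at the midpoint of
#' each color segment (10, 30, 50, 70, 90), giving the AGP metric values
#' a window in that segment is expected to show.
#'
#' @param fit a [polynomial_models()] result.
#' @return data frame: one row per segment, one column per metric fitted
#'   against the single score.
#' @export
segment_agp_table <- function(fit) {
  stopifnot(inherits(fit, "cgm_polyfit"))
  sel <- which(fit$score == "single")
  if (!length(sel)) stop("no single-score models in fit", call. = FALSE)
  mids <- c(dark_red = 10, red = 30, orange = 50, yellow = 70, green = 90)
  co_cols <- grep("^c[0-9]+$", names(fit), value = TRUE)
  out <- data.frame(segment = names(mids), score_midpoint = unname(mids))
  for (i in sel) {
    co <- as.numeric(fit[i, co_cols])
    out[[fit$metric[i]]] <-
      vapply(mids, function(x) sum(co * x^(seq_along(co) - 1)),
             numeric(1))
  }
  rownames(out) <- NULL
  out
}

#' Cohort-level calibration of the scoring model
#'
#' Bundles the cohort procedures: refit normalization maxima from daily
#' indices, label each window by consensus-target fulfillment, select
#' the ROC cutoff at the FPR bound, compute the score-vs-AGP Spearman
#' matrix and the polynomial models with their per-segment AGP table.
#'
#' @param scores list of `cgm_score` objects (one per patient), or a
#'   combined per-window data frame with score and AGP columns.
#' @param daily_indices optional combined daily-index data frame (with
#'   `cohort` column) for normalization refitting; extracted from
#'   `scores` when those are `cgm_score` objects.
#' @param targets a [target_set()].
#' @param fpr_bound acceptable false positive rate, default 0.025.
#' @param percentile percentile for [fit_normalization()], or `NULL` to
#'   skip refitting.
#' @param degree polynomial degree for [polynomial_models()].
#' @return object of class `cgm_calibration`: `windows` (with a
#'   `fulfilled` column), `roc`, `correlations`, `models`,
#'   `segment_table`, `fitted_params`.
#' @export
calibrate_cgm <- function(scores, daily_indices = NULL,
                          targets = target_set(), fpr_bound = 0.025,
                          percentile = 0.98, degree = 2) {
  if (is.data.frame(scores)) {
    windows <- scores
  } else {
    stopifnot(length(scores) >= 2)
    windows <- do.call(rbind, lapply(scores, function(s) s$windows))
    if (is.null(daily_indices))
      daily_indices <- do.call(rbind, lapply(scores, function(s)
        cbind(s$daily, cohort = s$cohort)))
  }
  windows$fulfilled <- targets_fulfilled(windows, targets)
  roc <- roc_cutoff(windows$single, windows$fulfilled, fpr_bound)
  cors <- correlation_matrix(windows)
  models <- polynomial_models(windows, degree = degree)
  fitted_params <- if (!is.null(percentile) && !is.null(daily_indices))
    fit_normalization(daily_indices, percentile)
  structure(list(windows = windows, roc = roc, correlations = cors,
                 models = models, segment_table = segment_agp_table(models),
                 fitted_params = fitted_params, targets = targets),
            class = "cgm_calibration")
}

#' @export
print.cgm_calibration <- function(x, ...) {
  cat(sprintf("CGM score calibration over %d windows (%.1f%% fulfilled)\n",
              nrow(x$windows), 100 * mean(x$windows$fulfilled)))
  print(x$roc)
  cat("\n")
  print(x$correlations)
  if (!is.null(x$fitted_params)) { cat("\nRefitted "); print(x$fitted_params) }
  invisible(x)
}
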