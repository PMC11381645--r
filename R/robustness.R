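#' Select full-availability multi-day sets
#'
#' Finds alignments of `set_length` consecutive calendar days (default
#' 30) in which every day reaches the per-day availability floor and the
#' whole set reaches the period floor (both default 90%). These sets act
#' as "full data" baselines for the missing-data experiments; the score
#' of the undegraded set is the true score.
#'
#' @param days a `cgm_days` object.
#' @param set_length set size in days, default 30.
#' @param min_day_availability,min_period_availability availability
#'   floors, both default 0.90.
#' @param overlap if `FALSE` (default) greedily returns non-overlapping
#'   sets; if `TRUE` returns every qualifying alignment.
#' @return list of `cgm_days` objects of `set_length` days each (possibly
#'   empty).
#' @export
select_full_sets <- function(days, set_length = 30L,
                             min_day_availability = 0.90,
                             min_period_availability = 0.90,
                             overlap = FALSE) {
  stopifnot(inherits(days, "cgm_days"))
  if (length(days) == 0) return(list())
  days <- days[order(days$date)]
  sets <- list()
  d <- days$date
  last_end <- as.Date("1900-01-01")
  for (i in seq_len(length(days))) {
    s <- d[i]; e <- s + set_length - 1
    if (!overlap && s <= last_end) next
    member <- which(d >= s & d <= e)
    if (length(member) != set_length) next          # gaps in the calendar
    if (any(days$availability[member] < min_day_availability)) next
    if (mean(days$availability[member]) < min_period_availability) next
    sets[[length(sets) + 1L]] <- days[member]
    if (!overlap) last_end <- e
  }
  sets
}

#' Specify one degradation level
#'
#' Two protocols reduce data availability: `random_slots` keeps a
#' uniformly random fraction of the observed 15-minute slots;
#' `whole_days` removes a number of uniformly chosen whole days.
#'
#' @param protocol `"random_slots"` or `"whole_days"`.
#' @param retained_fraction fraction of observed slots kept
#'   (`random_slots`), in `(0, 1]`.
#' @param omitted_days number of whole days removed (`whole_days`).
#' @param seed integer seed making the degradation deterministic.
#' @return list of class `degradation_spec`.
#' @export
degradation_spec <- function(protocol = c("random_slots", "whole_days"),
                             retained_fraction = NULL,
                             omitted_days = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  if (protocol == "random_slots") {
    stopifnot(!is.null(retained_fraction), is.null(omitted_days),
              retained_fraction > 0, retained_fraction <= 1)
  } else {
    stopifnot(!is.null(omitted_days), is.null(retained_fraction),
              omitted_days >= 0)
  }
  structure(list(protocol = protocol,
                 retained_fraction = retained_fraction,
                 omitted_days = omitted_days, seed = as.integer(seed)),
            class = "degradation_spec")
}

#' Default degradation levels
#'
#' `random_slots` retains 10% to 80% of observed slots in steps of 10;
#' `whole_days` omits 1 to 29 days in steps of 3.
#'
#' @return list of [degradation_spec()] objects (seeds all 1; the
#'   experiment reseeds per replicate).
#' @export
default_degradation_levels <- function() {
  c(lapply(seq(0.1, 0.8, by = 0.1), function(f)
      degradation_spec("random_slots", retained_fraction = f)),
    lapply(seq(1L, 29L, by = 3L), function(k)
      degradation_spec("whole_days", omitted_days = k)))
}

#' Degrade a day set according to a specification
#'
#' Degradation never invents data: the observed slots of the result are
#' a subset of the input's. With the same spec (including seed) the
#' result is bit-reproducible.
#'
#' @param set a `cgm_days` object (typically from [select_full_sets()]).
#' @param spec a [degradation_spec()].
#' @return a `cgm_days` object with additional slots set to missing.
#' @export
degrade <- function(set, spec) {
  stopifnot(inherits(set, "cgm_days"), inherits(spec, "degradation_spec"))
  grid <- set$grid
  with_seed(spec$seed, {
    if (spec$protocol == "random_slots") {
      obs <- which(!is.na(grid))
      n_keep <- round(spec$retained_fraction * length(obs))
      drop <- if (n_keep < length(obs))
        sample(obs, length(obs) - n_keep) else integer()
      grid[drop] <- NA_real_
    } else {
      k <- min(spec$omitted_days, nrow(grid))
      if (k > 0) grid[sample(nrow(grid), k), ] <- NA_real_
    }
  })
  new_cgm_days(set$date, grid, set$patient_id, set$cohort)
}

# Score one (possibly degraded) day set as a single window: re-apply the
# daily availability filter and aggregate all surviving days. Returns
# NULL when the set is unscorable.
score_day_set <- function(set, cohort, params = normalization_params(),
                          hypo_subset_fraction = 0.5,
                          min_day_availability = 0.70) {
  kept <- filter_days(set, min_day_availability)
  if (length(kept) == 0) return(NULL)
  idx <- daily_indices(kept)
  daily <- normalize_daily(idx[, c("lbgi", "hbgi", "gvp")], params, cohort)
  if (!any(stats::complete.cases(daily))) return(NULL)
  aggregate_period(daily, hypo_subset_fraction)
}

#' Missing-data robustness experiment
#'
#' For each degradation level and replicate, degrades every full set,
#' rescores it as a single window over the surviving days and compares
#' with the set's true score: the
#' score difference (degraded minus true; positive = falsely improved)
#' and whether the lowest-scoring dimension is preserved. Degraded sets
#' with no scorable day are excluded from the accuracy denominator and
#' counted separately.
#'
#' @param sets list of `cgm_days` from [select_full_sets()].
#' @param levels list of [degradation_spec()] levels (default
#'   [default_degradation_levels()]).
#' @param replicates degradation replicates per set and level.
#' @param seed root seed; per (level, replicate, set) seeds derive from
#'   it, so the full experiment is reproducible.
#' @param cohort cohort label used for normalization (default: each
#'   set's own tag).
#' @param params,hypo_subset_fraction passed to the scoring pipeline.
#' @param min_day_availability daily availability floor applied when
#'   rescoring degraded sets. Defaults to 0: a degraded set is scored
#'   from all remaining data, since heavy random-slot degradation leaves
#'   every day below the standard 70% floor while still carrying
#'   information; pass 0.70 to reuse the strict production filter.
#' @return object of class `cgm_robustness`: `results` (long form, one
#'   row per set x level x replicate) and `summary` (per level: mean and
#'   SD of the score difference, lowest-dimension accuracy, unscorable
#'   count).
#' @export
robustness_experiment <- function(sets,
                                  levels = default_degradation_levels(),
                                  replicates = 1L, seed = 1L,
                                  cohort = NULL,
                                  params = normalization_params(),
                                  hypo_subset_fraction = 0.5,
                                  min_day_availability = 0) {
  stopifnot(length(sets) >= 1)
  truth <- lapply(sets, function(s)
    score_day_set(s, if (is.null(cohort)) s$cohort else cohort, params,
                  hypo_subset_fraction, min_day_availability))
  ok <- !vapply(truth, is.null, logical(1))
  sets <- sets[ok]; truth <- truth[ok]
  rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[[li]]
    for (rep_i in seq_len(replicates)) {
      for (si in seq_along(sets)) {
        spec <- lev
        spec$seed <- derive_seed(seed, li * 1000003 + rep_i * 1009 + si)
        deg <- degrade(sets[[si]], spec)
        sc <- score_day_set(deg,
                            if (is.null(cohort)) sets[[si]]$cohort
                            else cohort,
                            params, hypo_subset_fraction,
                            min_day_availability)
        level_value <- if (lev$protocol == "random_slots")
          lev$retained_fraction else lev$omitted_days
        rows[[length(rows) + 1L]] <- data.frame(
          set_id = si, protocol = lev$protocol, level = level_value,
          replicate = rep_i,
          true_score = truth[[si]]$single,
          degraded_score = if (is.null(sc)) NA_real_ else sc$single,
          true_dimension = truth[[si]]$lowest_dimension,
          degraded_dimension = if (is.null(sc)) NA_character_
                               else sc$lowest_dimension,
          scorable = !is.null(sc))
      }
    }
  }
  results <- do.call(rbind, rows)
  results$score_difference <- results$degraded_score - results$true_score
  results$dimension_match <-
    results$degraded_dimension == results$true_dimension
  agg <- split(results, list(results$protocol, results$level),
               drop = TRUE)
  summary <- do.call(rbind, lapply(agg, function(g) {
    sc <- g[g$scorable, ]
    data.frame(protocol = g$protocol[1], level = g$level[1],
               n = nrow(g), n_unscorable = sum(!g$scorable),
               mean_difference = mean(sc$score_difference),
               sd_difference = stats::sd(sc$score_difference),
               dimension_accuracy = mean(sc$dimension_match))
  }))
  summary <- summary[order(summary$protocol, summary$level), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, seed = seed,
                 replicates = replicates),
            class = "cgm_robustness")
}

#' @export
print.cgm_robustness <- function(x, ...) {
  cat(sprintf("Missing-data robustness: %d comparisons, %d replicate(s)\n",
              nrow(x$results), x$replicates))
  print(x$summary, digits = 3)
  invisible(x)
}

#' @export
plot.cgm_robustness <- function(x, protocol = "random_slots", ...) {
  s <- x$summary[x$summary$protocol == protocol, ]
  if (!nrow(s)) stop("no results for protocol ", protocol, call. = FALSE)
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  xlab <- if (protocol == "random_slots") "retained fraction"
          else "omitted days"
  plot(s$level, s$mean_difference, type = "b", xlab = xlab,
       ylab = "mean score difference", ...)
  graphics::abline(h = 0, lty = 2)
  plot(s$level, s$dimension_accuracy, type = "b", ylim = c(0, 1),
       xlab = xlab, ylab = "lowest-dimension accuracy", ...)
  invisible(x)
}
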