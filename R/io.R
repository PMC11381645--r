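#' Describe the layout of a delimited CGM export
#'
#' CGM vendors export long-format tables that differ only in column names,
#' delimiter, timestamp format and glucose unit. A dialect captures those
#' choices so [read_cgm_file()] can ingest any of them.
#'
#' @param preset optional name of a built-in preset: `"generic_mmol"`
#'   (columns `time`, `glucose`, comma separated, mmol/L) or
#'   `"generic_mgdl"` (same layout, mg/dL). Explicit arguments override
#'   preset fields.
#' @param time_col,glucose_col column names holding the timestamp and the
#'   glucose reading.
#' @param sep field delimiter.
#' @param time_format `strptime()` format of the timestamp column.
#' @param unit glucose unit, `"mmol/L"` or `"mg/dL"`.
#' @return an object of class `cgm_dialect`.
#' @examples
#' cgm_dialect("generic_mgdl")
#' cgm_dialect(time_col = "ts", glucose_col = "bg", sep = "\t",
#'             unit = "mg/dL")
#' @export
cgm_dialect <- function(preset = NULL, time_col = "time",
                        glucose_col = "glucose", sep = ",",
                        time_format = "%Y-%m-%d %H:%M:%S",
                        unit = "mmol/L") {
  if (!is.null(preset)) {
    presets <- list(
      generic_mmol = list(unit = "mmol/L"),
      generic_mgdl = list(unit = "mg/dL")
    )
    if (!preset %in% names(presets))
      stop("unknown dialect preset: ", preset, call. = FALSE)
    if (missing(unit)) unit <- presets[[preset]]$unit
  }
  if (!unit %in% c("mmol/L", "mg/dL"))
    stop("unknown glucose unit: ", unit,
         " (expected 'mmol/L' or 'mg/dL')", call. = FALSE)
  structure(list(time_col = time_col, glucose_col = glucose_col, sep = sep,
                 time_format = time_format, unit = unit),
            class = "cgm_dialect")
}

new_cgm_series <- function(time, glucose, unit, patient_id = "unknown",
                           cohort = "adult") {
  stopifnot(cohort %in% c("adult", "pediatric"))
  out <- data.frame(time = time, glucose = glucose)
  attr(out, "unit") <- unit
  attr(out, "patient_id") <- patient_id
  attr(out, "cohort") <- cohort
  class(out) <- c("cgm_series", "data.frame")
  out
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf("CGM series: patient %s (%s), %d samples in %s\n",
              attr(x, "patient_id"), attr(x, "cohort"), nrow(x),
              attr(x, "unit")))
  if (nrow(x) > 0)
    cat(sprintf("  from %s to %s\n", format(min(x$time)),
                format(max(x$time))))
  invisible(x)
}

#' Read a raw CGM export into a glucose series
#'
#' Reads a delimited long-format CGM file, parses timestamps, sorts by time
#' and collapses duplicated timestamps to their mean reading. The returned
#' series keeps the file's glucose unit; conversion to mg/dL happens at
#' resampling time.
#'
#' @param path path to a delimited text file.
#' @param dialect a [cgm_dialect()] describing the file layout.
#' @param patient_id,cohort metadata attached to the series; `cohort` is
#'   `"adult"` or `"pediatric"` and selects the HBGI normalization maximum
#'   downstream.
#' @return a `cgm_series`: a data frame with columns `time` (POSIXct) and
#'   `glucose`, unit-tagged via attributes.
#' @seealso [resample_to_grid()], [write_cgm_file()]
#' @export
read_cgm_file <- function(path, dialect = cgm_dialect(),
                          patient_id = basename(path), cohort = "adult") {
  stopifnot(inherits(dialect, "cgm_dialect"))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0) {
    warning("empty CGM file: ", path, call. = FALSE)
    return(new_cgm_series(as.POSIXct(character(), tz = "UTC"), numeric(),
                          dialect$unit, patient_id, cohort))
  }
  for (col in c(dialect$time_col, dialect$glucose_col))
    if (!col %in% names(raw))
      stop("column '", col, "' not found in ", path, call. = FALSE)
  tm <- as.POSIXct(raw[[dialect$time_col]], format = dialect$time_format,
                   tz = "UTC")
  if (anyNA(tm)) {
    bad <- which(is.na(tm)) + 1L   # +1 for the header line
    stop("unparseable timestamp(s) in ", path, " at line(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  gl <- suppressWarnings(as.numeric(raw[[dialect$glucose_col]]))
  if (anyNA(gl)) {
    bad <- which(is.na(gl)) + 1L
    stop("non-numeric glucose in ", path, " at line(s) ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  if (any(gl <= 0))
    stop("non-positive glucose reading in ", path, call. = FALSE)
  ord <- order(tm)
  tm <- tm[ord]; gl <- gl[ord]
  # collapse duplicate timestamps to their mean
  if (anyDuplicated(tm)) {
    agg <- tapply(gl, as.numeric(tm), mean)
    tm2 <- as.POSIXct(as.numeric(names(agg)), origin = "1970-01-01",
                      tz = "UTC")
    gl <- as.numeric(agg)
    tm <- tm2
  }
  new_cgm_series(tm, gl, dialect$unit, patient_id, cohort)
}

#' Write a glucose series as a delimited CGM export
#'
#' Inverse of [read_cgm_file()]: emits the same long format the reader
#' accepts, enabling round-trip tests and interchange with other tools.
#'
#' @param series a `cgm_series`.
#' @param path output file path.
#' @param dialect a [cgm_dialect()]; the series is converted to the
#'   dialect's unit on write.
#' @export
write_cgm_file <- function(series, path, dialect = cgm_dialect()) {
  stopifnot(inherits(series, "cgm_series"))
  g <- series$glucose
  if (attr(series, "unit") != dialect$unit) {
    g <- if (dialect$unit == "mg/dL") mmol_to_mgdl(g) else mgdl_to_mmol(g)
  }
  out <- data.frame(format(series$time, dialect$time_format), g)
  names(out) <- c(dialect$time_col, dialect$glucose_col)
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

new_cgm_days <- function(date, grid, patient_id = "unknown",
                         cohort = "adult") {
  stopifnot(is.matrix(grid), ncol(grid) == SLOTS_PER_DAY,
            nrow(grid) == length(date))
  availability <- rowSums(!is.na(grid)) / SLOTS_PER_DAY
  structure(list(date = date, grid = grid, availability = availability,
                 patient_id = patient_id, cohort = cohort),
            class = "cgm_days")
}

#' @export
length.cgm_days <- function(x) length(x$date)

#' @export
`[.cgm_days` <- function(x, i) {
  new_cgm_days(x$date[i], x$grid[i, , drop = FALSE], x$patient_id,
               x$cohort)
}

#' @export
print.cgm_days <- function(x, ...) {
  cat(sprintf("CGM day profiles: patient %s (%s), %d day(s)\n",
              x$patient_id, x$cohort, length(x)))
  if (length(x) > 0)
    cat(sprintf("  %s .. %s, mean availability %.1f%%\n",
                format(min(x$date)), format(max(x$date)),
                100 * mean(x$availability)))
  invisible(x)
}

#' @export
as.data.frame.cgm_days <- function(x, ...) {
  slots <- sprintf("g%02d%02d", rep(0:23, each = 4), c(0, 15, 30, 45))
  grid <- as.data.frame(x$grid)
  names(grid) <- slots
  cbind(data.frame(patient_id = x$patient_id, date = x$date,
                   availability = x$availability), grid)
}

#' Harmonize a glucose series onto the daily 15-minute grid
#'
#' CGM sensors report at 1-15 minute intervals; all scoring is defined on a
#' common 15-minute grid. Each calendar day covered by the series becomes a
#' profile of 96 slots; a slot holds the mean of all samples falling in the
#' left-closed interval `[slot_start, slot_start + 15 min)`, converted to
#' mg/dL, or `NA` when no sample falls in it. Readings outside the sensor
#' reporting range are clamped to its boundaries after unit conversion.
#'
#' @param series a `cgm_series` from [read_cgm_file()] or
#'   [simulate_patient()].
#' @param clamp length-2 numeric sensor reporting range in mg/dL
#'   (default `c(39, 400)`), or `NULL` to disable clamping.
#' @return a `cgm_days` object: dates, a days x 96 glucose matrix (mg/dL)
#'   and per-day availability fractions.
#' @examples
#' s <- simulate_patient(sim_config(days_per_patient = 3, seed = 1), 1)
#' resample_to_grid(s)
#' @export
resample_to_grid <- function(series, clamp = SENSOR_RANGE) {
  stopifnot(inherits(series, "cgm_series"))
  if (nrow(series) == 0) stop("cannot resample an empty series",
                              call. = FALSE)
  g <- series$glucose
  if (attr(series, "unit") == "mmol/L") g <- mmol_to_mgdl(g)
  if (!is.null(clamp)) g <- pmin(pmax(g, clamp[1]), clamp[2])
  day <- as.Date(series$time, tz = "UTC")
  secs <- as.numeric(series$time) %% 86400
  slot <- floor(secs / (SLOT_MINUTES * 60)) + 1L   # 1..96, left-closed bins
  dates <- sort(unique(day))
  grid <- matrix(NA_real_, nrow = length(dates), ncol = SLOTS_PER_DAY)
  di <- match(day, dates)
  means <- tapply(g, list(di, slot), mean)
  grid[cbind(as.integer(rep(rownames(means), ncol(means))),
             as.integer(rep(colnames(means), each = nrow(means))))] <-
    as.numeric(means)
  new_cgm_days(dates, grid, attr(series, "patient_id"),
               attr(series, "cohort"))
}

#' Drop days with insufficient data availability
#'
#' Days with less than the required fraction of their 96 slots observed are
#' excluded from analysis (default 70%).
#'
#' @param days a `cgm_days` object.
#' @param min_availability retained days have availability
#'   `>= min_availability`; default 0.70.
#' @return the retained subset, still a `cgm_days` object.
#' @export
filter_days <- function(days, min_availability = 0.70) {
  stopifnot(inherits(days, "cgm_days"),
            min_availability >= 0, min_availability <= 1)
  days[days$availability >= min_availability]
}

#' Enumerate multi-day scoring windows
#'
#' Slides a window of `window_length` calendar days one day at a time over
#' the span of the retained day profiles and keeps every window whose
#' period availability reaches the threshold. Period availability is the
#' total number of observed slots contributed by retained member days
#' divided by `window_length * 96`, so calendar days excluded by the daily
#' filter count as fully missing.
#'
#' @param days a `cgm_days` object, normally already passed through
#'   [filter_days()].
#' @param window_length window size in calendar days (default 14).
#' @param min_period_availability minimum period availability (default
#'   0.70).
#' @return a data frame of class `cgm_windows` with columns `start_date`,
#'   `end_date`, `n_days`, `availability`; the member-day indices of each
#'   window are kept in `attr(, "day_index")`.
#' @export
enumerate_windows <- function(days, window_length = 14L,
                              min_period_availability = 0.70) {
  stopifnot(inherits(days, "cgm_days"), window_length >= 1)
  if (length(days) == 0 || is.unsorted(days$date))
    days <- days[order(days$date)]
  empty <- data.frame(start_date = as.Date(character()),
                      end_date = as.Date(character()),
                      n_days = integer(), availability = numeric())
  if (length(days) == 0) {
    attr(empty, "day_index") <- list()
    class(empty) <- c("cgm_windows", "data.frame")
    return(empty)
  }
  slots <- round(days$availability * SLOTS_PER_DAY)
  last_start <- max(days$date) - window_length + 1
  starts <- if (min(days$date) > last_start) as.Date(character())
            else seq(min(days$date), last_start, by = 1)
  keep <- list(); idx <- list()
  for (s in as.list(starts)) {
    e <- s + window_length - 1
    member <- which(days$date >= s & days$date <= e)
    avail <- sum(slots[member]) / (window_length * SLOTS_PER_DAY)
    if (avail >= min_period_availability) {
      keep[[length(keep) + 1L]] <-
        data.frame(start_date = s, end_date = e,
                   n_days = length(member), availability = avail)
      idx[[length(idx) + 1L]] <- member
    }
  }
  out <- if (length(keep)) do.call(rbind, keep) else empty
  rownames(out) <- NULL
  attr(out, "day_index") <- idx
  class(out) <- c("cgm_windows", "data.frame")
  out
}
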