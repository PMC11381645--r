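#' Constants of the blood-glucose risk model
#'
#' The low and high blood glucose indices are built on a symmetrizing
#' transform `f(BG) = a * ((ln BG)^b - c)` (BG in mg/dL) whose root sits
#' near 112.5 mg/dL, with risk `r(BG) = scale * f(BG)^2`. The published
#' constants are fixed here and overridable only explicitly.
#'
#' @param a,b,c dimensionless constants of the symmetrization.
#' @param scale multiplier applied to the squared transform.
#' @return a list of class `risk_constants`.
#' @export
risk_constants <- function(a = 1.509, b = 1.084, c = 5.381, scale = 10) {
  structure(list(a = a, b = b, c = c, scale = scale),
            class = "risk_constants")
}

#' Symmetrizing risk transform of blood glucose
#'
#' Maps glucose (mg/dL) onto a scale where hypoglycemia is negative and
#' hyperglycemia positive, with a steeper penalty on the hypoglycemic
#' side. The unique root is `exp(c^(1/b))`, about 112.52 mg/dL.
#'
#' @param glucose numeric vector, mg/dL, strictly positive.
#' @param constants a [risk_constants()] object.
#' @return signed numeric vector `f(glucose)`.
#' @examples
#' risk_transform(risk_root())  # 0
#' risk_transform(50)           # about -1.5
#' @export
risk_transform <- function(glucose, constants = risk_constants()) {
  if (any(glucose <= 0, na.rm = TRUE))
    stop("glucose must be strictly positive", call. = FALSE)
  constants$a * (log(glucose)^constants$b - constants$c)
}

#' @rdname risk_transform
#' @export
risk_root <- function(constants = risk_constants()) {
  exp(constants$c^(1 / constants$b))
}

#' Daily low and high blood glucose indices
#'
#' Per observed slot the risk is `r = scale * f(BG)^2`, attributed to the
#' low index when `f < 0` and to the high index when `f > 0`; LBGI and
#' HBGI are the means of the low and high attributions over all observed
#' slots of the day.
#'
#' @param values numeric vector of slot glucose values in mg/dL, `NA` for
#'   missing slots.
#' @param constants a [risk_constants()] object.
#' @return named numeric vector `c(lbgi = , hbgi = )`, both `>= 0`.
#' @examples
#' daily_lbgi_hbgi(rep(risk_root(), 96))  # c(0, 0)
#' daily_lbgi_hbgi(rep(50, 96))           # lbgi ~ 22.5
#' @export
daily_lbgi_hbgi <- function(values, constants = risk_constants()) {
  v <- values[!is.na(values)]
  if (length(v) == 0)
    stop("LBGI/HBGI undefined for an all-missing day", call. = FALSE)
  f <- risk_transform(v, constants)
  r <- constants$scale * f^2
  c(lbgi = mean(ifelse(f < 0, r, 0)), hbgi = mean(ifelse(f > 0, r, 0)))
}

#' Daily glycemic variability percentage
#'
#' GVP is the excess length of the glucose trace over a perfectly flat
#' trace of the same duration: `(L / L0 - 1) * 100`, where `L` sums
#' `sqrt(dt^2 + dg^2)` over consecutive observed slot pairs (`dt` in
#' minutes, `dg` in mg/dL) and `L0` is the elapsed time those pairs cover.
#' Pairs separated by missing slots use the true elapsed time, so missing
#' data dilutes rather than inflates the curve length.
#'
#' @param values numeric vector of slot glucose values in mg/dL, `NA` for
#'   missing slots.
#' @param interval_min slot duration in minutes (default 15).
#' @return GVP in percent, `>= 0`.
#' @examples
#' daily_gvp(rep(120, 96))          # 0: flat trace
#' daily_gvp(120 + 15 * rep(c(0, 1), 48))  # sawtooth, about 41.4
#' @export
daily_gvp <- function(values, interval_min = SLOT_MINUTES) {
  obs <- which(!is.na(values))
  if (length(obs) < 2)
    stop("GVP undefined with fewer than 2 observed slots", call. = FALSE)
  dt <- diff(obs) * interval_min
  dg <- diff(values[obs])
  L <- sum(sqrt(dt^2 + dg^2))
  L0 <- sum(dt)
  (L / L0 - 1) * 100
}

#' Per-day index table for a set of day profiles
#'
#' Computes LBGI, HBGI and GVP for every day profile. Days with too few
#' observed slots for a metric get `NA` there.
#'
#' @param days a `cgm_days` object.
#' @param constants a [risk_constants()] object.
#' @return data frame with columns `date`, `lbgi`, `hbgi`, `gvp`,
#'   `availability`.
#' @export
daily_indices <- function(days, constants = risk_constants()) {
  stopifnot(inherits(days, "cgm_days"))
  n <- length(days)
  lbgi <- hbgi <- gvp <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- days$grid[i, ]
    if (any(!is.na(v))) {
      lh <- daily_lbgi_hbgi(v, constants)
      lbgi[i] <- lh[["lbgi"]]; hbgi[i] <- lh[["hbgi"]]
    }
    if (sum(!is.na(v)) >= 2) gvp[i] <- daily_gvp(v)
  }
  data.frame(date = days$date, lbgi = lbgi, hbgi = hbgi, gvp = gvp,
             availability = days$availability)
}

#' Standard ambulatory glucose profile metrics
#'
#' Time-in-range percentages over all observed slots, with the consensus
#' thresholds 3.9 / 10.0 / 13.9 / 3.0 mmol/L (converted once to mg/dL).
#' Below-range and above-range are strict inequalities and time in range
#' is the closed complement, so `tir + tar + tbr = 100` exactly. CV% uses
#' the population standard deviation; GMI is the standard linear map from
#' mean glucose, `3.31 + 0.02392 * mean`.
#'
#' @param x a `cgm_days` object or a numeric vector of mg/dL glucose
#'   values (`NA` = missing).
#' @return one-row data frame: `tir`, `tar`, `tsar`, `tbr`, `tsbr` (% of
#'   observed time), `cv` (%), `gmi` (%), `mean_glucose` (mg/dL).
#' @examples
#' agp_metrics(rep(100, 96))  # TIR 100, GMI 5.702
#' @export
agp_metrics <- function(x) {
  v <- if (inherits(x, "cgm_days")) as.numeric(t(x$grid)) else as.numeric(x)
  v <- v[!is.na(v)]
  if (length(v) == 0)
    stop("AGP metrics undefined without observed slots", call. = FALSE)
  th <- AGP_THRESHOLDS
  pct <- function(cond) 100 * mean(cond)
  m <- mean(v)
  sd_pop <- sqrt(mean((v - m)^2))
  data.frame(
    tir  = pct(v >= th$tbr & v <= th$tar),
    tar  = pct(v > th$tar),
    tsar = pct(v > th$tsar),
    tbr  = pct(v < th$tbr),
    tsbr = pct(v < th$tsbr),
    cv   = 100 * sd_pop / m,
    gmi  = 3.31 + 0.02392 * m,
    mean_glucose = m
  )
}
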