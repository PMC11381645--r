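# Independent brute-force oracles and small fixture builders. The
# oracles deliberately use scalar loops and the published formulas
# directly, not the package's vectorized code paths.

oracle_risk <- function(g) 1.509 * ((log(g))^1.084 - 5.381)

oracle_lbgi_hbgi <- function(values) {
  rl <- rh <- numeric(0)
  for (v in values) {
    if (is.na(v)) next
    f <- oracle_risk(v)
    r <- 10 * f^2
    rl <- c(rl, if (f < 0) r else 0)
    rh <- c(rh, if (f > 0) r else 0)
  }
  c(mean(rl), mean(rh))
}

oracle_gvp <- function(values, interval = 15) {
  obs <- which(!is.na(values))
  L <- 0; L0 <- 0
  for (i in seq_len(length(obs) - 1)) {
    dt <- (obs[i + 1] - obs[i]) * interval
    dg <- values[obs[i + 1]] - values[obs[i]]
    L <- L + sqrt(dt^2 + dg^2)
    L0 <- L0 + dt
  }
  (L / L0 - 1) * 100
}

# One day profile (96 slots) as a cgm_days object.
make_day <- function(values, date = as.Date("2023-03-01"),
                     cohort = "adult") {
  stopifnot(length(values) == 96)
  cgmscore:::new_cgm_days(date, matrix(values, nrow = 1),
                          "TEST", cohort)
}

# n consecutive full days, each filled with `value` (or a vector of 96).
make_days <- function(n, value = 120, start = as.Date("2023-03-01"),
                      cohort = "adult") {
  grid <- matrix(rep(rep_len(value, 96), n), nrow = n, byrow = TRUE)
  cgmscore:::new_cgm_days(seq(start, by = 1, length.out = n), grid,
                          "TEST", cohort)
}

# A sawtooth day oscillating +/- amp around `center` every slot.
sawtooth_day <- function(amp, center = 150) {
  make_day(center + amp * rep(c(0, 1), 48))
}

# Write a small CSV CGM export; returns the path.
write_fixture_csv <- function(times, glucose, col_time = "time",
                              col_gluc = "glucose") {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(times, glucose)
  names(df) <- c(col_time, col_gluc)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
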