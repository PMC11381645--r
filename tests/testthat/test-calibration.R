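test_that("normalization refit recovers closed-form percentiles", {
  set.seed(3)
  n <- 4000
  idx <- data.frame(lbgi = runif(n, 0, 10), hbgi = runif(n, 0, 40),
                    gvp = runif(n, 10, 110),
                    cohort = rep(c("adult", "pediatric"), n / 2))
  p <- fit_normalization(idx, 0.98)
  expect_equal(p$lbgi_max, 9.8, tolerance = 0.05)     # 98th pct of U(0,10)
  expect_equal(p$gvp_max, 10 + 0.98 * 100, tolerance = 0.5)
  expect_equal(p$lbgi_min, 0)
  expect_equal(p$gvp_min, 20)
  # percentile 1.0 returns the stratum maxima
  p1 <- fit_normalization(idx, 1.0)
  expect_equal(p1$lbgi_max, max(idx$lbgi))
  expect_equal(p1$hbgi_max_adult, max(idx$hbgi[idx$cohort == "adult"]))
  # single-cohort input flags the missing stratum
  expect_warning(pa <- fit_normalization(idx[idx$cohort == "adult", ]),
                 "stratum")
  expect_true(is.na(pa$hbgi_max_pediatric))
  expect_false(is.na(pa$hbgi_max_adult))
  expect_error(fit_normalization(idx[0, ]), "empty")
})

test_that("target fulfillment follows the consensus thresholds and
           boundary conventions", {
  perfect <- data.frame(tir = 100, tar = 0, tsar = 0, tbr = 0, tsbr = 0,
                        cv = 20)
  expect_true(targets_fulfilled(perfect))
  expect_false(targets_fulfilled(transform(perfect, tir = 69.9)))
  boundary <- data.frame(tir = 70, tar = 25, tsar = 5, tbr = 4, tsbr = 1,
                         cv = 36)
  expect_true(targets_fulfilled(boundary))
  expect_false(targets_fulfilled(transform(boundary, tbr = 4.01)))
  # monotone: improving any single metric never flips TRUE -> FALSE
  better <- list(transform(boundary, tir = 80),
                 transform(boundary, tar = 10),
                 transform(boundary, tbr = 1),
                 transform(boundary, cv = 30))
  for (b in better) expect_true(targets_fulfilled(b))
})

test_that("roc_cutoff enumerates the 4-point ROC exactly", {
  r <- roc_cutoff(c(90, 85, 70, 60), c(TRUE, TRUE, FALSE, FALSE), 0.025)
  expect_equal(r$auc, 1.0)
  expect_equal(r$threshold, 85)  # smallest score with no false positive
  expect_equal(r$fpr_at_threshold, 0)
  expect_equal(r$sensitivity, 1.0)
  expect_equal(r$specificity, 1.0)
  expect_equal(r$accuracy, 1.0)
  expect_error(roc_cutoff(c(1, 2), c(TRUE, TRUE)), "both")
})

test_that("ROC AUC equals the Mann-Whitney statistic and pROC agrees", {
  set.seed(44)
  for (i in 1:5) {
    n <- 60
    lab <- runif(n) < 0.4
    sc <- round(runif(n, 0, 100) + 25 * lab, 1)  # ties likely
    r <- roc_cutoff(sc, lab, fpr_bound = 1)
    u <- 0
    for (p in sc[lab]) for (q in sc[!lab])
      u <- u + (p > q) + 0.5 * (p == q)
    expect_equal(r$auc, u / (sum(lab) * sum(!lab)), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(45)
  lab <- runif(100) < 0.5
  sc <- runif(100, 0, 100) + 20 * lab
  r <- roc_cutoff(sc, lab, fpr_bound = 1)
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-10)
})

test_that("ROC threshold is monotone non-increasing in the FPR bound and
           uninformative scores give AUC near 0.5", {
  set.seed(46)
  lab <- runif(400) < 0.5
  sc <- runif(400, 0, 100) + 15 * lab
  th <- vapply(c(0.01, 0.05, 0.2, 0.5, 1),
               function(b) roc_cutoff(sc, lab, b)$threshold, numeric(1))
  expect_true(all(diff(th) <= 1e-12))
  sc_null <- runif(400, 0, 100)
  r0 <- roc_cutoff(sc_null, lab, 1)
  expect_lt(abs(r0$auc - 0.5), 0.08)
})

test_that("correlation matrix handles self, reversed and constant columns", {
  set.seed(8)
  n <- 40
  w <- data.frame(hypo = runif(n, 0, 100))
  w$hyper <- w$hypo; w$var <- runif(n, 0, 100); w$single <- runif(n)
  w$tir <- w$hypo                 # identical ranks -> r = 1
  w$tar <- -w$hypo                # reversed ranks -> r = -1
  w$tsar <- runif(n); w$tbr <- runif(n); w$tsbr <- runif(n)
  w$cv <- runif(n); w$gmi <- runif(n)
  w$mean_glucose <- rep(5, n)     # constant -> NA
  cm <- correlation_matrix(w)
  expect_equal(cm$r["hypo", "tir"], 1)
  expect_equal(cm$r["hypo", "tar"], -1)
  expect_true(all(is.na(cm$r[, "mean_glucose"])))
  expect_lt(cm$p["hypo", "tir"], 1e-10)
  expect_equal(dim(cm$r), c(4, 8))
})

test_that("polynomial models interpolate exact quadratics and nest", {
  set.seed(2)
  x <- seq(0, 100, length.out = 30)
  jit <- function() x + rnorm(30)
  w <- data.frame(single = x, hypo = x, hyper = x, var = x,
                  tir = 2 + 0.5 * x - 0.003 * x^2,
                  tar = 90 - 0.8 * x, tsar = jit(), tbr = jit(),
                  tsbr = jit(), cv = jit(), gmi = jit(),
                  mean_glucose = jit())
  fit <- polynomial_models(w, degree = 2)
  row <- fit[fit$score == "single" & fit$metric == "tir", ]
  expect_equal(c(row$c0, row$c1, row$c2), c(2, 0.5, -0.003),
               tolerance = 1e-8)
  expect_equal(row$r2, 1, tolerance = 1e-12)
  # degree 1 on linear data equals the simple regression slope
  fit1 <- polynomial_models(w, pairs = data.frame(score = "single",
                                                  metric = "tar"),
                            degree = 1)
  expect_equal(fit1$c1, unname(coef(lm(tar ~ single, w))[2]),
               tolerance = 1e-10)
  # pure noise: r2 near 0 at large n
  set.seed(10)
  wn <- data.frame(single = runif(3000, 0, 100), tir = runif(3000))
  fn <- polynomial_models(wn, pairs = data.frame(score = "single",
                                                 metric = "tir"))
  expect_lt(fn$r2, 0.01)
})

test_that("segment table evaluates single-score models at midpoints", {
  set.seed(3)
  x <- seq(0, 100, length.out = 30)
  jit <- function() x + rnorm(30)
  w <- data.frame(single = x, hypo = x, hyper = x, var = x,
                  tir = 1 + 0.9 * x, tar = jit(), tsar = jit(),
                  tbr = jit(), tsbr = jit(), cv = jit(), gmi = jit(),
                  mean_glucose = jit())
  tab <- segment_agp_table(polynomial_models(w, degree = 2))
  expect_equal(tab$segment,
               c("dark_red", "red", "orange", "yellow", "green"))
  expect_equal(tab$tir, 1 + 0.9 * c(10, 30, 50, 70, 90),
               tolerance = 1e-8)
})

test_that("cohort calibration bundles ROC, correlations and models", {
  co <- simulate_cohort(sim_config(n_patients = 12,
                                   days_per_patient = 20, seed = 19))
  scores <- lapply(seq_along(co$series), function(i)
    score_cgm(co$series[[i]], cohort = co$truth$cohort[i]))
  cal <- calibrate_cgm(scores)
  expect_s3_class(cal, "cgm_calibration")
  expect_lte(cal$roc$fpr_at_threshold, 0.025)
  expect_gte(cal$roc$specificity, 0.975)
  expect_true(all(dim(cal$correlations$r) == c(4, 8)))
  expect_s3_class(cal$fitted_params, "cgm_norm_params")
  expect_equal(nrow(cal$segment_table), 5)
  expect_output(print(cal), "calibration")
})
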