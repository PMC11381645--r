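# Shared graded synthetic cohort for the end-to-end checks, built once
# per test run (50 patients x 30 days at the generator defaults).
.cohort_cache <- new.env(parent = emptyenv())

acceptance_cohort <- function(seed = 101) {
  key <- paste0("s", seed)
  if (is.null(.cohort_cache[[key]])) {
    co <- simulate_cohort(sim_config(seed = seed))
    scores <- lapply(seq_along(co$series), function(i)
      score_cgm(co$series[[i]], cohort = co$truth$cohort[i]))
    windows <- do.call(rbind, lapply(scores, function(s) s$windows))
    .cohort_cache[[key]] <- list(cohort = co, scores = scores,
                                 windows = windows)
  }
  .cohort_cache[[key]]
}
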