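make_ft <- function(e, dt = 0.1) {
  structure(list(efficiency = e, raw_efficiency = e,
                 frame_index = seq_along(e), time_s = (seq_along(e) - 1) * dt,
                 valid_mask = rep(TRUE, length(e)), frame_interval_s = dt,
                 leakage_used = 0, bleach_frame = NULL, meta = list()),
            class = "fret_trace")
}

test_that("deterministic prototypes classify verbatim", {
  # constant + mild noise -> steady
  set.seed(1)
  expect_identical(classify_trace(make_ft(0.3 + rnorm(300, 0, 0.03)))$label,
                   "steady")
  # noiseless square wave 0.2 <-> 0.55 -> dynamicI
  sq <- make_ft(rep(c(rep(0.2, 15), rep(0.55, 15)), 10))
  expect_identical(classify_trace(sq)$label, "dynamicI")
  # noiseless baseline 0.3 with spikes to 0.9 -> dynamicII
  sp <- rep(0.3, 300); for (s in seq(30, 270, by = 40)) sp[s:(s + 4)] <- 0.9
  expect_identical(classify_trace(make_ft(sp))$label, "dynamicII")
  # both patterns -> dynamicI_II
  mix <- rep(0.2, 300)
  mix[30:60] <- 0.5; mix[120:125] <- 0.9; mix[200:230] <- 0.5
  expect_identical(classify_trace(make_ft(mix))$label, "dynamicI_II")
  # downward excursions from a high baseline (2R geometry) -> dynamicI
  dn <- rep(0.6, 300); dn[50:80] <- 0.3; dn[150:170] <- 0.3
  expect_identical(classify_trace(make_ft(dn))$label, "dynamicI")
})

test_that("short traces return the unclassified sentinel", {
  cl <- classify_trace(make_ft(rep(0.3, 30)))
  expect_identical(cl$label, "unclassified")
  fr <- summarize_fractions(list(cl, classify_trace(make_ft(rep(0.3, 300)))))
  expect_equal(fr$n, 1L)
})

test_that("classification thresholds are robust across the documented A range", {
  ft <- sim_fret("POT1_dynamicII", 15, seed = 2)
  for (A in c(0.12, 0.15, 0.18)) {
    labs <- label_of(lapply(ft, classify_trace, amplitude_threshold = A))
    expect_true(all(fold3(labs) == "dynamicII"))
  }
})

test_that("ground-truth labels are recovered on mixture ensembles", {
  mix <- c(POT1_steady_4R = 0.40, POT1_dynamicI = 0.35, POT1_dynamicII = 0.25)
  for (seed in c(3, 4)) {
    ts <- simulate_ensemble(mix, 150, seed = seed)
    truth <- vapply(ts, function(tr) tr$meta$label, "")
    truth3 <- c(POT1_steady_4R = "steady", POT1_dynamicI = "dynamicI",
                POT1_dynamicII = "dynamicII")[truth]
    pred <- fold3(label_of(classify_traces(process_traces(ts))))
    expect_gte(mean(pred == truth3), 0.90)
  }
})

test_that("fraction of dynamic time grows with the spike rate", {
  fracs <- vapply(c(5, 2.5, 1.2), function(base_dwell) {
    m <- two_state_model(0.25, 0.85, base_dwell, 0.63)
    ft <- process_traces(trace_set(lapply(1:20, function(i) {
      p <- simulate_state_path(m, 61, seed = i)
      render_trace(p, photophysics(), excitation_scheme(), 600,
                   seed = 300 + i)
    })))
    mean(vapply(classify_traces(ft), function(cl) cl$fraction_dynamic_time, 0))
  }, 0)
  expect_true(all(diff(fracs) > 0))
})

test_that("summarize_fractions reports coherent bootstrap intervals", {
  cls <- lapply(1:40, function(i) classify_trace(make_ft(rep(0.3, 100) +
                                                           rnorm(100, 0, 0.02))))
  fr <- summarize_fractions(cls, seed = 5)
  expect_equal(unname(fr$fractions["steady"]), 1)
  expect_equal(unname(fr$ci_upper["steady"] - fr$ci_lower["steady"]), 0)
  expect_equal(sum(fr$fractions), 1)
  rep1 <- summarize_fractions(cls, seed = 7)
  rep2 <- summarize_fractions(cls, seed = 7)
  expect_identical(rep1$ci_lower, rep2$ci_lower)
})

test_that("compare_fractions matches the closed-form two-sample t test", {
  same <- compare_fractions(c(0.2, 0.3, 0.25), c(0.2, 0.3, 0.25))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  sep <- compare_fractions(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9))
  expect_lt(sep$p, 1e-3)
  # textbook pair, cross-checked against the t CDF directly
  a <- c(0.62, 0.55, 0.60, 0.58); b <- c(0.48, 0.52, 0.45, 0.50)
  got <- compare_fractions(a, b)
  sp <- sqrt(((3) * var(a) + (3) * var(b)) / 6)
  t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 4 + 1 / 4))
  expect_equal(got$t, t_ref, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_ref), 6), tolerance = 1e-12)
  expect_error(compare_fractions(0.5, c(0.4, 0.5)), "replicates")
})

test_that("donor-only traces are excluded upstream without touching labels", {
  ts <- simulate_preset("POT1_dynamicI", 10, seed = 8)
  sch <- excitation_scheme(10, 1, 10, repeat_cycle = TRUE)
  donor_only <- lapply(1:5, function(i) {
    p <- simulate_state_path(state_model(1e-9, matrix(0, 1, 1)), 61, seed = i)
    render_trace(p, photophysics(acceptor_bleach_rate = 1e3), sch, 600,
                 seed = 40 + i)
  })
  keep <- !vapply(donor_only, flag_donor_only, TRUE)
  expect_true(all(!keep))
  labs1 <- fold3(label_of(classify_traces(process_traces(ts))))
  combined <- trace_set(c(unclass(ts), donor_only))
  flagged <- vapply(combined, function(tr)
    tryCatch(flag_donor_only(tr), error = function(e) FALSE), TRUE)
  labs2 <- fold3(label_of(classify_traces(process_traces(combined[!flagged]))))
  expect_identical(labs1, labs2)
})
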