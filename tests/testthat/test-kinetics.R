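test_that("square-wave excursions all dwell exactly one second", {
  e <- rep(c(rep(0.2, 10), rep(0.55, 10)), 15)
  ft <- structure(list(efficiency = e, raw_efficiency = e,
                       frame_index = seq_along(e),
                       time_s = (seq_along(e) - 1) * 0.1,
                       valid_mask = rep(TRUE, length(e)),
                       frame_interval_s = 0.1, leakage_used = 0,
                       bleach_frame = NULL, meta = list()),
                  class = "fret_trace")
  dw <- extract_dwells(list(ft))
  expect_true(all(dw == 1.0))
})

test_that("the truncated MLE is unbiased across decay constants", {
  for (tau in c(0.25, 0.63, 1, 2.51, 5)) {
    set.seed(round(100 * tau))
    d <- rexp(1000, 1 / tau)
    f <- fit_exponential(d, floor_s = 0, seed = 1)
    expect_lt(abs(f$tau_s - tau), 3 * tau / sqrt(1000))
  }
})

test_that("truncation correction removes the detection-floor bias", {
  set.seed(2)
  d <- rexp(20000, 1 / 0.63)
  observed <- d[d >= 0.2]              # detector loses short events
  corrected <- fit_exponential(observed, floor_s = 0.2, seed = 1)$tau_s
  uncorrected <- mean(observed)
  expect_lt(abs(corrected - 0.63), 0.03)
  expect_gt(uncorrected, 0.63 + 0.15)  # biased high without the correction
})

test_that("frame-quantized dwells need the geometric MLE (lattice oracle)", {
  set.seed(3)
  for (tau in c(0.63, 2.51)) {
    T <- rexp(30000, 1 / tau)
    N <- lattice_measure(T, cov = 0.43)
    d <- N * 0.1
    d <- d[N >= 2]
    attr(d, "frame_s") <- 0.1
    geo <- fit_exponential(d, floor_s = 0.3, seed = 1, n_boot = 50)$tau_s
    cont <- fit_exponential(d, floor_s = 0.3, seed = 1, n_boot = 50,
                            frame_s = 0)$tau_s
    expect_lt(abs(geo - tau) / tau, 0.02)
    expect_gt(abs(cont - tau), abs(geo - tau))   # continuous formula is worse
  }
})

test_that("right-censored exposure enters the MLE as survival time", {
  set.seed(4)
  d <- rexp(2000, 1 / 2)
  cens <- pmin(rexp(500, 1 / 2), 1.5)           # censored at 1.5 s
  dd <- d
  attr(dd, "censored_s") <- cens
  f <- fit_exponential(dd, floor_s = 0, seed = 1)
  manual <- (sum(d) + sum(cens)) / length(d)
  expect_equal(f$tau_s, manual)
  expect_equal(f$n_censored, 500L)
})

test_that("degenerate equal dwells are flagged with a zero-width interval", {
  f <- fit_exponential(rep(2, 20), seed = 1)
  expect_true(f$degenerate)
  expect_equal(f$tau_s, 2)
  expect_equal(diff(f$ci95), 0)
  expect_error(fit_exponential(rexp(5)), ">= 10")
})

test_that("binned least-squares fitting reproduces the decay constant", {
  set.seed(5)
  d <- rexp(5000, 1 / 2.5)
  f <- fit_exponential(d, method = "binned_lsq", floor_s = 0, seed = 1,
                       n_boot = 100)
  expect_lt(abs(f$tau_s - 2.5) / 2.5, 0.1)
})

test_that("dynamic-class dwell recovery hits the preset decay constants", {
  targets <- c(POT1_dynamicI = 2.51, POT1_dynamicII = 0.63, POT1_2R = 2.31)
  tols <- c(0.31, 0.14, 0.29)
  for (i in seq_along(targets)) {
    ft <- sim_fret(names(targets)[i], 120, seed = 20 + i)
    f <- fit_exponential(extract_dwells(ft, classify_traces(ft)), seed = 1,
                         n_boot = 100)
    expect_lt(abs(f$tau_s - targets[[i]]), tols[i])
  }
})

test_that("time_to_first_binding honours the irreversibility window", {
  mk <- function(e) structure(
    list(efficiency = e, raw_efficiency = e, frame_index = seq_along(e),
         time_s = (seq_along(e) - 1) * 0.1, valid_mask = rep(TRUE, length(e)),
         frame_interval_s = 0.1, leakage_used = 0, bleach_frame = NULL,
         meta = list(flow_frame = 100L)),
    class = "fret_trace")
  # clean step at frame 150, flow at 100 -> 5.0 s
  e <- c(rep(0.65, 149), rep(0.3, 151))
  expect_equal(time_to_first_binding(mk(e)), 5.0)
  # transient 3-frame dip recovers; later stable drop is the answer
  e2 <- rep(0.65, 300); e2[120:122] <- 0.3; e2[200:300] <- 0.3
  expect_equal(time_to_first_binding(mk(e2)), 10.0)
  # never binds
  expect_true(is.na(time_to_first_binding(mk(rep(0.65, 300)))))
})

test_that("flow-ensemble binding times are exponential at the design rate", {
  ts <- simulate_preset("flow_POT1", 150, seed = 30, n_frames = 1200,
                        concentration_nM = 5)   # rate 0.4 / s
  ft <- process_traces(ts)
  waits <- vapply(ft, function(f) {
    v <- time_to_first_binding(f)
    if (is.null(v)) NA_real_ else v
  }, 0)
  waits <- waits[!is.na(waits)]
  rate <- 0.08 * 5
  expect_lt(abs(mean(waits) - 1 / rate), 3 * (1 / rate) / sqrt(length(waits)))
  ks <- suppressWarnings(stats::ks.test(waits, "pexp", rate))
  expect_gt(ks$p.value, 0.01)
})

test_that("bound-fraction time courses return k_obs with its scale", {
  set.seed(6)
  t <- c(30, 60, 120, 240, 480, 960)
  f_true <- 1 - exp(-0.01 * t)
  f_obs <- rbinom(length(t), 200, f_true) / 200
  fit <- bound_fraction_timecourse(t, f_obs)
  expect_lt(abs(fit$k_obs - 0.01) / 0.01, 0.2)
  # slow-binding scenario: ~50% at 3 min, ~90% at 20 min
  fit2 <- bound_fraction_timecourse(c(60, 180, 600, 1200),
                                    c(0.21, 0.50, 0.90, 0.99))
  expect_equal(1 - exp(-fit2$k_obs * 180), 0.5, tolerance = 0.1)
  expect_equal(1 - exp(-fit2$k_obs * 1200), 0.99, tolerance = 0.1)
  # already saturated at t = 0 -> flagged out of range
  sat <- bound_fraction_timecourse(c(0, 10, 20, 30), c(1, 1, 1, 1))
  expect_true(sat$out_of_range)
})

test_that("fit_kon recovers the association slope through the origin", {
  conc <- c(1, 2, 5, 10, 25)
  exact <- fit_kon(conc, 0.08 * conc)
  expect_equal(exact$kon_per_nM_per_s, 0.08)
  expect_equal(fit_kon(conc, rep(0, 5))$kon_per_nM_per_s, 0)
  set.seed(7)
  noisy <- fit_kon(conc, 0.08 * conc * (1 + rnorm(5, 0, 0.1)))
  expect_lt(abs(noisy$kon_per_nM_per_s - 0.08) / 0.08, 0.15)
})

test_that("estimate_kd_app solves the half-saturation identity", {
  conc <- c(0.2, 0.5, 1.5, 4, 10, 30)
  f <- conc / (conc + 1.5)
  expect_equal(estimate_kd_app(conc, f, n_boot = 0)$kd_app_nM, 1.5,
               tolerance = 1e-6)
  set.seed(8)
  fn <- rbinom(length(conc), 200, conc / (conc + 1.4)) / 200
  expect_lt(abs(estimate_kd_app(conc, fn, n_boot = 0)$kd_app_nM - 1.4), 0.3)
  expect_error(estimate_kd_app(conc, rep(0.99, 6), n_boot = 0),
               "unidentifiable")
})

test_that("PIFE steps are located and the ensemble rate recovered", {
  ts <- simulate_preset("flow_TRF2_PIFE", 120, seed = 40, n_frames = 1500)
  errs <- vapply(seq_along(ts), function(i) {
    ev <- detect_pife(ts[[i]])
    if (is.null(ev)) NA_real_ else ev$step_frame - ts[[i]]$meta$true_binding_frame
  }, 0)
  expect_gt(mean(!is.na(errs)), 0.85)
  expect_true(all(abs(errs[!is.na(errs)]) <= 4))
  # no-enhancement trace -> NULL
  flat <- simulate_preset("flow_POT1", 1, seed = 41, n_frames = 600)[[1]]
  expect_null(detect_pife(flat))
  pr <- pife_binding_rate(ts)
  expect_lt(abs(pr$rate_per_s - 0.13), 0.025)
})
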