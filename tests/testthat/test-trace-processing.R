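test_that("compute_fret applies the leakage-corrected ratiometric formula", {
  tr <- intensity_trace(donor = c(100, 900, 70), acceptor = c(100, 72, 30))
  e0 <- compute_fret(tr, leakage = 0, background = 0,
                     truncate_bleach = FALSE)$efficiency
  expect_equal(e0[1], 0.5)
  e8 <- compute_fret(tr, leakage = 0.08, background = 0,
                     truncate_bleach = FALSE)$efficiency
  expect_equal(e8[2], 0)                       # donor-only maps to exactly 0
  e10 <- compute_fret(tr, leakage = 0.1, background = 0,
                      truncate_bleach = FALSE)$efficiency
  expect_equal(e10[3], 23 / 93)                # direct arithmetic
})

test_that("non-positive total intensity masks the frame instead of erroring", {
  tr <- intensity_trace(donor = c(100, 0, 100), acceptor = c(100, 0, 100))
  ft <- compute_fret(tr, leakage = 0, background = 10,
                     truncate_bleach = FALSE)
  expect_equal(ft$valid_mask, c(TRUE, FALSE, TRUE))
})

test_that("compute_fret inverts the renderer exactly for any leakage", {
  m <- two_state_model(0.25, 0.7, 0.8, 0.8)
  p <- simulate_state_path(m, 41, seed = 11)
  for (lk in c(0, 0.04, 0.08, 0.12)) {
    tr <- render_trace(p, photophysics(noise_sd = 0, leakage = lk,
                                       background = 35),
                       excitation_scheme(), 400, seed = 12)
    ft <- compute_fret(tr, leakage = lk, background = 35)
    truth <- tr$meta$true_fret[ft$frame_index]
    expect_lt(max(abs(ft$efficiency - truth)), 1e-9)
  }
})

test_that("estimate_leakage recovers the simulated coefficient unbiasedly", {
  m <- state_model(1e-9, matrix(0, 1, 1))    # donor-only molecules
  for (lk in c(0, 0.04, 0.08, 0.12)) {
    traces <- lapply(1:100, function(i) {
      p <- simulate_state_path(m, 21, seed = i)
      render_trace(p, photophysics(leakage = lk), excitation_scheme(),
                   200, seed = 500 + i)
    })
    est <- estimate_leakage(trace_set(traces), background = 50)
    expect_lt(abs(est - lk), 0.005)
  }
  expect_error(estimate_leakage(trace_set(list())), "at least one")
})

test_that("flag_donor_only reads the red-excitation block", {
  m <- state_model(0.5, matrix(0, 1, 1))
  p <- simulate_state_path(m, 21, seed = 1)
  sch <- excitation_scheme(10, 1, 10, repeat_cycle = TRUE)
  with_acc <- render_trace(p, photophysics(), sch, 84, seed = 2)
  expect_false(flag_donor_only(with_acc))
  # acceptor bleached before any red block: red frames at background
  no_acc <- render_trace(p, photophysics(acceptor_bleach_rate = 1e3),
                         sch, 84, seed = 3)
  expect_true(flag_donor_only(no_acc))
  green_only <- render_trace(p, photophysics(), excitation_scheme(10, 0, 0),
                             84, seed = 4)
  expect_error(flag_donor_only(green_only), "red-excitation")
})

test_that("detect_bleach finds injected steps and degenerate cases", {
  m <- state_model(0.5, matrix(0, 1, 1))
  hits <- 0L; total <- 0L
  for (i in 1:20) {
    p <- simulate_state_path(m, 61, seed = i)
    tr <- render_trace(p, photophysics(donor_bleach_rate = 0.03),
                       excitation_scheme(), 600, seed = 700 + i)
    tb <- tr$meta$donor_bleach_frame
    if (is.na(tb) || tb < 30 || tb > 570) next
    total <- total + 1L
    b <- detect_bleach(tr)
    if (!is.null(b) && abs(b - tb) <= 2) hits <- hits + 1L
  }
  expect_gt(total, 5L)
  expect_equal(hits, total)
  # no bleach -> NULL
  tr2 <- render_trace(simulate_state_path(m, 61, seed = 5), photophysics(),
                      excitation_scheme(), 600, seed = 6)
  expect_null(detect_bleach(tr2))
  # all-background trace -> index 0
  set.seed(8)
  tr3 <- intensity_trace(rnorm(200, 50, 5), rnorm(200, 50, 5))
  expect_equal(detect_bleach(tr3, background = 50), 0L)
})

test_that("masked frames never reach downstream statistics", {
  m <- state_model(0.5, matrix(0, 1, 1))
  p <- simulate_state_path(m, 61, seed = 9)
  tr <- render_trace(p, photophysics(noise_sd = 0, background = 0),
                     excitation_scheme(), 600, seed = 10)
  ft <- compute_fret(tr, leakage = 0, background = 0)
  # poison half the frames with a sentinel and mask them
  poison <- seq(1, length(ft$efficiency), by = 2)
  ft$efficiency[poison] <- 77
  ft$valid_mask[poison] <- FALSE
  h <- build_histogram(list(ft), frames_per_molecule = Inf)
  expect_equal(h$mids[which.max(h$density)], 0.51, tolerance = 0.03)
  cl <- classify_trace(ft)
  expect_identical(cl$label, "steady")
})

test_that("ensemble background pooling removes single-frame jitter", {
  m <- state_model(0.5, matrix(0, 1, 1))
  traces <- trace_set(lapply(1:50, function(i) {
    p <- simulate_state_path(m, 21, seed = i)
    render_trace(p, photophysics(background = 50), excitation_scheme(),
                 200, seed = 900 + i)
  }))
  expect_lt(abs(ensemble_background(traces) - 50), 3 * 83.3 / sqrt(100))
})
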