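test_that("histogram density integrates to one and finds the free-G4 peak", {
  ft <- sim_fret("G4_free", 200, seed = 1, n_frames = 40)
  h <- build_histogram(ft)
  expect_equal(sum(h$density) * h$bin_width, 1)
  mode_at <- h$mids[which.max(h$density)]
  expect_lt(abs(mode_at - 0.65), 0.03)
  # degenerate: a single exact value occupies one bin
  ft1 <- list(structure(list(efficiency = rep(0.5, 20),
                             raw_efficiency = rep(0.5, 20),
                             frame_index = 1:20, time_s = (0:19) / 10,
                             valid_mask = rep(TRUE, 20),
                             frame_interval_s = 0.1, leakage_used = 0,
                             bleach_frame = NULL, meta = list()),
                        class = "fret_trace"))
  h1 <- build_histogram(ft1)
  expect_equal(sum(h1$counts > 0), 1L)
  expect_error(build_histogram(list()), "empty")
})

test_that("Gaussian fits recover peak centers and mixture weights", {
  ft <- sim_fret("G4_free", 300, seed = 2, n_frames = 40)
  g <- fit_gaussians(build_histogram(ft), 1)
  expect_lt(abs(g$components$mean - 0.65), 0.01)

  ftb <- sim_fret("POT1_steady_4R", 300, seed = 3, n_frames = 40)
  gb <- fit_gaussians(build_histogram(ftb), 1)
  expect_lt(abs(gb$components$mean - 0.30), 0.01)

  mixed <- simulate_ensemble(c(G4_free = 0.5, POT1_steady_4R = 0.5), 400,
                             seed = 4, n_frames = 40)
  g2 <- fit_gaussians(build_histogram(process_traces(mixed)), 2)
  expect_equal(g2$components$mean, c(0.30, 0.65), tolerance = 0.02)
  w <- g2$components$weight / sum(g2$components$weight)
  expect_lt(abs(w[1] - 0.5), 0.05)
})

test_that("fitted means are stable under half-bin phase shifts", {
  ft <- sim_fret("G4_free", 300, seed = 5, n_frames = 40)
  h1 <- build_histogram(ft, bin_width = 0.02, limits = c(-0.1, 1.1))
  h2 <- build_histogram(ft, bin_width = 0.02, limits = c(-0.11, 1.11))
  m1 <- fit_gaussians(h1, 1)$components$mean
  m2 <- fit_gaussians(h2, 1)$components$mean
  expect_lt(abs(m1 - m2), 0.005)
})

test_that("bound_fraction sums component weights inside the bound window", {
  ft <- sim_fret("POT1_steady_4R", 200, seed = 6, n_frames = 40)
  g <- fit_gaussians(build_histogram(ft), 1)
  expect_equal(bound_fraction(g), 1)
  expect_equal(bound_fraction(g, bound_window = c(0.55, 0.75)), 0)
})

test_that("bound_fraction is an unbiased estimator across mixing fractions", {
  for (p in c(0.1, 0.5, 0.9)) {
    mixed <- simulate_ensemble(c(POT1_steady_4R = p, G4_free = 1 - p), 500,
                               seed = round(1000 * p), n_frames = 40)
    g <- fit_gaussians(build_histogram(process_traces(mixed)), 2,
                       init_means = c(0.3, 0.65), equal_sd = TRUE)
    expect_lt(abs(bound_fraction(g) - p), 0.03 + 3 * sqrt(p * (1 - p) / 500))
  }
})

test_that("event-synchronized heatmaps sharpen the binding transition", {
  ts <- simulate_preset("flow_POT1", 60, seed = 7, n_frames = 600,
                        concentration_nM = 2.5)   # slow binding: waits spread
  ft <- process_traces(ts)
  events <- vapply(seq_along(ft), function(i) {
    tb <- time_to_first_binding(ft[[i]])
    if (is.na(tb)) return(NA_integer_)
    fr <- ts[[i]]$meta$flow_frame + round(tb / 0.1)
    which.min(abs(ft[[i]]$frame_index - fr))   # index into green frames
  }, 0L)
  hm_sync <- build_heatmap(ft, sync = "event", event_frames = events,
                           time_window = c(-5, 20))
  hm_raw <- build_heatmap(ft, sync = "none")
  # at the synchronized event the occupancy concentrates at the bound level
  col0 <- which.min(abs(hm_sync$time_s - 1))
  em <- sum(hm_sync$fret_mids * hm_sync$density[, col0])
  expect_lt(em, 0.45)
  colpre <- which.min(abs(hm_sync$time_s - (-2)))
  expect_gt(sum(hm_sync$fret_mids * hm_sync$density[, colpre]), 0.55)
  # unsynchronized columns around the mean binding time mix both levels
  tcol <- which.min(abs(hm_raw$time_s - 15))
  v_raw <- sum((hm_raw$fret_mids - sum(hm_raw$fret_mids * hm_raw$density[, tcol]))^2 *
                 hm_raw$density[, tcol])
  v_sync <- sum((hm_sync$fret_mids - em)^2 * hm_sync$density[, col0])
  expect_gt(v_raw, v_sync)
  # every populated column is normalized
  expect_true(all(abs(colSums(hm_sync$density)[!hm_sync$empty_columns] - 1) < 1e-9))
})

test_that("single constant trace gives a single horizontal heatmap band", {
  ft <- sim_fret("POT1_steady_4R", 1, seed = 8, n_frames = 200,
                 phys = photophysics(noise_sd = 0))
  hm <- build_heatmap(ft)
  occupied <- rowSums(hm$density) > 0
  expect_lte(diff(range(hm$fret_mids[occupied])), 0.06)
})

test_that("dynamic-range heatmap histograms report the occupied FRET span", {
  ftI <- sim_fret("POT1_dynamicI", 40, seed = 9)
  hI <- fret_range_heatmap(ftI)
  expect_gte(hI$span[1], 0.1)
  expect_lte(hI$span[2], 0.7)
  ftL <- sim_fret("TRF2_POT1_4R_ladder", 40, seed = 10)
  hL <- fret_range_heatmap(ftL)
  expect_gte(hL$span[2], 0.85)
  ftC <- sim_fret("POT1_steady_4R", 10, seed = 11,
                  phys = photophysics(noise_sd = 0))
  hC <- fret_range_heatmap(ftC, bin_size = 0.2)
  expect_equal(sum(hC$occupied_bins), 1L)
})
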