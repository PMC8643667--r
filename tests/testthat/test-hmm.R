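square_wave <- function(lo = 0.3, hi = 0.7, half_period = 10, n = 400) {
  rep(c(rep(lo, half_period), rep(hi, half_period)), length.out = n)
}

test_that("noiseless two-state data is fitted exactly", {
  x <- square_wave()
  f <- fit_hmm(x, 2, seed = 1)
  expect_equal(f$means, c(0.3, 0.7), tolerance = 1e-6)
  truth <- rep(c(rep(1L, 10), rep(2L, 10)), length.out = 400)
  expect_identical(f$viterbi_path, truth)
  expect_true(f$variance_floored)
  tr <- extract_transitions(f)
  expect_equal(nrow(tr), 39L)   # one boundary per half period
})

test_that("forward likelihood matches an independent log-space implementation", {
  set.seed(2)
  x <- square_wave() + rnorm(400, 0, 0.05)
  f <- fit_hmm(x, 2, seed = 2)
  ref <- naive_forward_loglik(x, f$means, f$sds, f$transition_matrix, f$initial)
  expect_equal(f$log_likelihood, ref, tolerance = 1e-9)
  # and for a 3-state model on the same data
  f3 <- fit_hmm(x, 3, seed = 3)
  ref3 <- naive_forward_loglik(x, f3$means, f3$sds, f3$transition_matrix,
                               f3$initial)
  expect_equal(f3$log_likelihood, ref3, tolerance = 1e-9)
})

test_that("noisy two-state traces recover means and per-frame rates", {
  ft <- sim_fret("TRF2_POT1_2Rduplex", 8, seed = 4)
  fits <- lapply(ft, fit_hmm, n_states = 2, seed = 5)
  for (f in fits) expect_equal(f$means, c(0.55, 0.80), tolerance = 0.04)
  # per-frame transition probability ~ rate * dt = 0.125; ensemble rate
  # within 20% of the simulated CTMC rate (dwells are 8 frames long)
  rates <- vapply(fits, function(f)
    -log(1 - f$transition_matrix[1, 2]) / 0.1, 0)
  expect_lt(abs(median(rates) - 1.25) / 1.25, 0.2)
})

test_that("overfitted state counts collapse back to the true model", {
  x <- square_wave()
  s <- select_states(x, k_range = 2:8, seed = 6)
  expect_equal(s$n_states, 2L)
  expect_equal(s$means, c(0.3, 0.7), tolerance = 0.01)
  ft <- sim_fret("TRF2_POT1_2Rduplex", 4, seed = 7)
  ks <- vapply(seq_along(ft), function(i)
    select_states(ft[[i]], seed = 7 + i)$n_states, 0L)
  expect_true(all(ks == 2L))
})

test_that("state-label permutations do not change the collapsed model", {
  set.seed(8)
  x <- square_wave() + rnorm(400, 0, 0.05)
  f <- fit_hmm(x, 3, seed = 8)
  perm <- c(3, 1, 2)
  inv <- order(perm)
  g <- f
  g$means <- f$means[perm]; g$sds <- f$sds[perm]
  g$transition_matrix <- f$transition_matrix[perm, perm]
  g$initial <- f$initial[perm]
  g$viterbi_path <- inv[f$viterbi_path]
  g$occupancy <- f$occupancy[perm]
  cf <- telodyn:::collapse_states(f)
  cg <- telodyn:::collapse_states(g)
  expect_equal(cf$means, cg$means, tolerance = 1e-9)
  expect_identical(cf$viterbi_path, cg$viterbi_path)
})

test_that("transition records carry levels and dwells with short runs absorbed", {
  f <- list(n_states = 2, means = c(0.3, 0.7), sds = c(0.05, 0.05),
            transition_matrix = diag(2), initial = c(1, 0),
            viterbi_path = c(rep(1L, 10), rep(2L, 10), rep(1L, 10)),
            log_likelihood = 0, occupancy = c(2 / 3, 1 / 3),
            efficiency = numeric(30), frame_interval_s = 0.1)
  class(f) <- "hmm_fit"
  tr <- extract_transitions(f)
  expect_equal(tr$e_before, c(0.3, 0.7))
  expect_equal(tr$e_after, c(0.7, 0.3))
  expect_equal(tr$dwell_before_s, c(1.0, 1.0))
  expect_identical(tr$censored_before, c(TRUE, FALSE))
  # single-frame blips are absorbed into the longer neighbour
  f$viterbi_path <- c(rep(1L, 10), 2L, rep(1L, 19))
  expect_equal(nrow(extract_transitions(f)), 0L)
  # constant path emits no records
  f$viterbi_path <- rep(1L, 30)
  expect_equal(nrow(extract_transitions(f)), 0L)
})

test_that("stationary chains balance upward and downward transition counts", {
  m <- two_state_model(0.3, 0.7, 1, 1)
  p <- simulate_state_path(m, 1001, seed = 9)
  tr <- render_trace(p, photophysics(noise_sd = 0, leakage = 0,
                                     background = 0),
                     excitation_scheme(10, 0, 0), 10000, seed = 10)
  ft <- compute_fret(tr, leakage = 0, background = 0)
  f <- fit_hmm(ft, 2, seed = 11)
  recs <- extract_transitions(f)
  n_up <- sum(recs$e_after > recs$e_before)
  n_dn <- sum(recs$e_after < recs$e_before)
  expect_lte(abs(n_up - n_dn), 1L)
})

test_that("the TDP separates ascending and descending steps", {
  one_up <- structure(data.frame(e_before = 0.3, e_after = 0.7,
                                 dwell_before_s = 1, censored_before = FALSE),
                      class = c("transition_records", "data.frame"))
  tdp <- build_tdp(one_up)
  expect_equal(sum(tdp$counts[upper.tri(tdp$counts)]), 1)
  expect_equal(sum(tdp$counts[lower.tri(tdp$counts)]), 0)
  expect_true(all(diag(tdp$counts) == 0))
  # reversible ensemble: triangle masses equal within sampling error
  ft <- sim_fret("TRF2_POT1_2Rduplex", 10, seed = 12)
  fits <- lapply(seq_along(ft), function(i) fit_hmm(ft[[i]], 2, seed = 12 + i))
  pooled <- pool_transitions(fits)
  tdp2 <- build_tdp(pooled)
  up <- sum(tdp2$counts[upper.tri(tdp2$counts)])
  dn <- sum(tdp2$counts[lower.tri(tdp2$counts)])
  expect_lt(abs(up - dn), 3 * sqrt(up + dn))
})

test_that("count_tdp_levels resolves the ladder and duplex level counts", {
  # transitions built from ground-truth paths (independent of the HMM)
  lad <- preset("TRF2_POT1_4R_ladder")$model
  mk_recs <- function(model, seed, n = 30) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      p <- simulate_state_path(model, 60, seed = seed + i)
      if (nrow(p) < 2) return(NULL)
      d <- path_dwells(p, drop_censored = FALSE)
      data.frame(e_before = model$fret_means[p$state[-nrow(p)]] +
                   rnorm(nrow(p) - 1, 0, 0.01),
                 e_after = model$fret_means[p$state[-1]] +
                   rnorm(nrow(p) - 1, 0, 0.01),
                 dwell_before_s = d$dwell_s[-nrow(d)],
                 censored_before = FALSE)
    }))
  }
  set.seed(13)
  recs <- mk_recs(lad, 100)
  lv <- count_tdp_levels(recs)
  expect_equal(lv$n_levels, 4L)
  expect_equal(lv$centers, c(0.35, 0.55, 0.70, 0.85), tolerance = 0.05)
  dup <- preset("TRF2_POT1_2Rduplex")$model
  recs2 <- mk_recs(dup, 300)
  lv2 <- count_tdp_levels(recs2)
  expect_equal(lv2$n_levels, 2L)
  expect_equal(lv2$centers, c(0.55, 0.80), tolerance = 0.05)
  expect_error(count_tdp_levels(recs[1:5, ]), "transitions")
})

test_that("level counting is stable across seeded replicates", {
  lad <- preset("TRF2_POT1_4R_ladder")$model
  counts <- vapply(1:50, function(r) {
    set.seed(r)
    recs <- do.call(rbind, lapply(1:8, function(i) {
      p <- simulate_state_path(lad, 60, seed = 5000 + 10 * r + i)
      data.frame(e_before = lad$fret_means[p$state[-nrow(p)]] +
                   rnorm(nrow(p) - 1, 0, 0.01),
                 e_after = lad$fret_means[p$state[-1]] +
                   rnorm(nrow(p) - 1, 0, 0.01))
    }))
    count_tdp_levels(recs)$n_levels
  }, 0L)
  expect_gte(mean(counts == 4L), 0.95)
})
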