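# Independent oracles kept deliberately separate from the package internals.

# Naive log-space forward algorithm (log-sum-exp), independent of the scaled
# C++ implementation it cross-checks.
naive_forward_loglik <- function(x, means, sds, A, init) {
  k <- length(means)
  logA <- log(A)
  la <- log(init) + dnorm(x[1], means, sds, log = TRUE)
  for (t in seq_along(x)[-1]) {
    la <- vapply(seq_len(k), function(j) {
      m <- la + logA[, j]
      mx <- max(m)
      mx + log(sum(exp(m - mx)))
    }, 0) + dnorm(x[t], means, sds, log = TRUE)
  }
  mx <- max(la)
  mx + log(sum(exp(la - mx)))
}

# Exact frame-quantized duration measurement: number of camera frames whose
# overlap with an interval of length T (uniform phase) is at least a
# fraction `cov` of the frame. Used as the lattice oracle for dwell
# estimators.
lattice_measure <- function(T, cov, dt = 0.1) {
  u <- runif(length(T)) * dt
  t0 <- u; t1 <- u + T
  n <- ceiling(t1 / dt)
  vapply(seq_along(T), function(i) {
    fr <- seq_len(n[i])
    ov <- pmin(fr * dt, t1[i]) - pmax((fr - 1) * dt, t0[i])
    sum(ov >= cov * dt)
  }, 0L)
}

# Simulate-and-process shorthand used across tests.
sim_fret <- function(preset, n, seed, n_frames = 600, phys = NULL, ...) {
  ts <- simulate_preset(preset, n, seed = seed, n_frames = n_frames,
                        phys = phys, ...)
  process_traces(ts)
}

label_of <- function(classes) vapply(classes, function(cl) cl$label, "")

# Fold mixed dynamicI_II into dynamicII (the three-way chart convention).
fold3 <- function(labels) ifelse(labels == "dynamicI_II", "dynamicII", labels)
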