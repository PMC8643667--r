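#' Fit a Gaussian-emission hidden Markov model to a FRET trace
#'
#' Baum-Welch maximum-likelihood fit of a stationary HMM with Gaussian
#' emissions to the valid efficiencies of one trace — the standard approach
#' for identifying statistically significant discrete FRET levels in noisy
#' single-molecule traces. Means are initialized by k-means; the fit is
#' restarted `n_restarts` times with distinct seeds and the best-likelihood
#' solution kept. The most-likely state path is decoded by Viterbi.
#'
#' Degenerate convergence (a state's variance collapsing onto repeated
#' values) is guarded by a variance floor of 1e-4 (SD 0.01) and flagged.
#'
#' @param trace a `fret_trace` (or bare numeric vector of efficiencies) with
#'   at least `min_frames` valid frames.
#' @param n_states number of states (2..8).
#' @param seed integer seed (restart seeds derive from it).
#' @param n_restarts independent EM restarts (default 5).
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @param min_frames minimum valid frames (default 100).
#' @return An object of class `hmm_fit`: list with `n_states`, `means`
#'   (ascending), `sds`, `transition_matrix` (per-frame probabilities, rows
#'   sum to 1), `initial`, `viterbi_path`, `log_likelihood`, `occupancy`
#'   (Viterbi fraction per state), `variance_floored`, `frame_interval_s`.
#' @export
fit_hmm <- function(trace, n_states, seed, n_restarts = 5,
                    max_iter = 300, tol = 1e-6, min_frames = 100) {
  stopifnot(n_states >= 2, n_states <= 8)
  x <- if (inherits(trace, "fret_trace")) valid_efficiency(trace) else as.numeric(trace)
  dt <- if (inherits(trace, "fret_trace")) trace$frame_interval_s else 0.1
  if (length(x) < min_frames)
    stop("HMM fitting requires >= ", min_frames, " valid frames")
  seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seeds[r])
    init <- hmm_init(x, n_states)
    fit <- .hmm_baum_welch(x, init$means, init$sds, init$transition,
                           init$initial, max_iter, tol, 0.01)
    if (is.null(best) || fit$log_likelihood > best$log_likelihood) best <- fit
  }
  ord <- order(best$means)
  means <- best$means[ord]; sds <- best$sds[ord]
  A <- best$transition[ord, ord, drop = FALSE]
  pi0 <- best$initial[ord]
  path <- .hmm_viterbi(x, means, sds, A, pi0)
  occ <- tabulate(path, nbins = n_states) / length(path)
  structure(list(n_states = n_states, means = means, sds = sds,
                 transition_matrix = A, initial = pi0,
                 viterbi_path = path,
                 log_likelihood = best$log_likelihood,
                 occupancy = occ,
                 variance_floored = isTRUE(best$variance_floored),
                 converged = isTRUE(best$converged),
                 efficiency = x, frame_interval_s = dt),
            class = "hmm_fit")
}

# k-means initialization: cluster centers as state means, pooled
# within-cluster SD (floored), sticky transition matrix, uniform start.
hmm_init <- function(x, k) {
  ux <- unique(x)
  if (length(ux) >= k) {
    km <- suppressWarnings(kmeans(x, centers = k, nstart = 3, iter.max = 50))
    means <- as.numeric(km$centers)
    sds <- rep(max(sqrt(mean(km$withinss) / max(length(x), 1)), 0.02), k)
  } else {
    means <- seq(min(x), max(x), length.out = k) + rnorm(k, 0, 0.01)
    sds <- rep(0.05, k)
  }
  A <- matrix(0.1 / (k - 1), k, k); diag(A) <- 0.9
  list(means = means, sds = sds, transition = A, initial = rep(1 / k, k))
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("hmm_fit:", x$n_states, "states, logLik", round(x$log_likelihood, 2),
      if (x$variance_floored) "(variance floored)" else "", "\n")
  print(data.frame(mean = x$means, sd = x$sds, occupancy = x$occupancy),
        digits = 3)
  invisible(x)
}

#' @export
plot.hmm_fit <- function(x, ...) {
  t <- (seq_along(x$efficiency) - 1) * x$frame_interval_s
  graphics::plot(t, x$efficiency, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "FRET efficiency", ylim = c(0, 1), ...)
  graphics::lines(t, x$means[x$viterbi_path], col = "red", lwd = 2)
  invisible(x)
}

#' Log-likelihood of a FRET series under an HMM
#'
#' Scaled forward-algorithm evaluation of `P(data | model)`; useful for
#' model comparison and cross-checks.
#'
#' @param x numeric efficiencies.
#' @param fit an `hmm_fit` (or list with `means`, `sds`,
#'   `transition_matrix`, `initial`).
#' @return log-likelihood.
#' @export
hmm_loglik <- function(x, fit) {
  .hmm_loglik(as.numeric(x), fit$means, fit$sds, fit$transition_matrix,
              fit$initial)
}

#' Fit across state counts, merge indistinct states, and collapse
#'
#' Applies more states than expected and lets the data decide: models are
#' fitted for each `k` in `k_range`, the fit minimising the Bayesian
#' information criterion is taken (raw likelihood grows monotonically with
#' `k` as extra states absorb emission noise, so an explicit complexity
#' penalty is required), fitted states whose means differ by less than
#' `merge_tol` are merged (occupancy-weighted), and states with Viterbi
#' occupancy below `min_occupancy` are discarded (their frames reassigned to
#' the nearest surviving state).
#'
#' @inheritParams fit_hmm
#' @param k_range candidate state counts (default 2:8).
#' @param merge_tol FRET separation below which states merge (default 0.07,
#'   set below the smallest reported inter-state gap).
#' @param min_occupancy minimum Viterbi occupancy to keep a state
#'   (default 0.02).
#' @return A collapsed `hmm_fit` (with `n_states` the collapsed count and
#'   extra `k_fitted` and `bic` fields).
#' @export
select_states <- function(trace, k_range = 2:8, seed = 1, merge_tol = 0.07,
                          min_occupancy = 0.02, n_restarts = 5, ...) {
  fits <- lapply(k_range, function(k)
    fit_hmm(trace, k, seed = seed + k, n_restarts = n_restarts, ...))
  n_obs <- length(fits[[1]]$efficiency)
  bic <- vapply(seq_along(fits), function(i) {
    k <- fits[[i]]$n_states
    n_par <- k * (k - 1) + 2 * k + (k - 1)   # transitions + emissions + start
    -2 * fits[[i]]$log_likelihood + n_par * log(n_obs)
  }, 0)
  best <- fits[[which.min(bic)]]
  out <- collapse_states(best, merge_tol = merge_tol,
                         min_occupancy = min_occupancy)
  out$k_fitted <- best$n_states
  out$bic <- min(bic)
  out
}

# Merge states closer than merge_tol (occupancy-weighted means), drop states
# with occupancy < min_occupancy, remap the Viterbi path and collapse the
# transition matrix accordingly.
collapse_states <- function(fit, merge_tol = 0.07, min_occupancy = 0.02) {
  means <- fit$means; sds <- fit$sds; occ <- fit$occupancy
  group <- seq_along(means)
  repeat {
    centers <- vapply(unique(group), function(gr) {
      w <- occ[group == gr]
      if (sum(w) > 0) sum(means[group == gr] * w) / sum(w) else mean(means[group == gr])
    }, 0)
    gids <- unique(group)
    if (length(gids) < 2L) break
    d <- abs(outer(centers, centers, "-")); diag(d) <- Inf
    mn <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[mn[1], mn[2]] >= merge_tol) break
    group[group == gids[mn[2]]] <- gids[mn[1]]
  }
  gids <- unique(group)
  gmap <- match(group, gids)
  k2 <- length(gids)
  occ2 <- vapply(seq_len(k2), function(i) sum(occ[gmap == i]), 0)
  means2 <- vapply(seq_len(k2), function(i) {
    w <- occ[gmap == i]
    if (sum(w) > 0) sum(means[gmap == i] * w) / sum(w) else mean(means[gmap == i])
  }, 0)
  sds2 <- vapply(seq_len(k2), function(i) {
    w <- pmax(occ[gmap == i], 1e-12)
    sqrt(sum(sds[gmap == i]^2 * w) / sum(w))
  }, 0)

  keep <- occ2 >= min_occupancy
  if (!any(keep)) keep[which.max(occ2)] <- TRUE
  kept_idx <- which(keep)
  # reassign dropped states to the nearest kept state by mean
  final_of_group <- vapply(seq_len(k2), function(i) {
    if (keep[i]) match(i, kept_idx) else which.min(abs(means2[kept_idx] - means2[i]))
  }, 0L)

  path2 <- final_of_group[gmap[fit$viterbi_path]]
  kf <- length(kept_idx)
  means_f <- means2[kept_idx]; sds_f <- sds2[kept_idx]
  ord <- order(means_f)
  remap <- match(seq_len(kf), ord)
  path_f <- remap[path2]
  means_f <- means_f[ord]; sds_f <- sds_f[ord]
  occ_f <- tabulate(path_f, nbins = kf) / length(path_f)

  # empirical per-frame transition matrix from the collapsed path
  A <- matrix(0, kf, kf)
  if (length(path_f) > 1) {
    for (t in seq_len(length(path_f) - 1L))
      A[path_f[t], path_f[t + 1L]] <- A[path_f[t], path_f[t + 1L]] + 1
  }
  rs <- rowSums(A)
  A <- A / ifelse(rs > 0, rs, 1)
  diag(A)[rs == 0] <- 1

  structure(list(n_states = kf, means = means_f, sds = sds_f,
                 transition_matrix = A,
                 initial = tabulate(path_f[1], nbins = kf),
                 viterbi_path = path_f,
                 log_likelihood = fit$log_likelihood,
                 occupancy = occ_f,
                 variance_floored = fit$variance_floored,
                 converged = fit$converged,
                 efficiency = fit$efficiency,
                 frame_interval_s = fit$frame_interval_s),
            class = "hmm_fit")
}
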