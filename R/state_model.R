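#' Define a multi-state FRET model with continuous-time kinetics
#'
#' A `state_model` couples a set of labelled FRET levels to a continuous-time
#' Markov chain (CTMC): each state has a mean FRET efficiency and the
#' `rate_matrix` holds per-second transition rates. It is the ground truth for
#' trajectory simulation and the target of HMM inference.
#'
#' @param fret_means numeric vector of state mean FRET efficiencies, each
#'   strictly inside (0, 1).
#' @param rate_matrix square matrix of per-second rates; off-diagonal entries
#'   are the state-to-state rates (>= 0) and each diagonal entry must equal
#'   minus its row sum of off-diagonals (conservative generator). For a
#'   single-state model use a 1x1 zero matrix.
#' @param labels optional character state labels.
#' @param initial_distribution starting-state probabilities; defaults to the
#'   stationary distribution of `rate_matrix` (uniform for one state).
#'
#' @return An object of class `state_model` with elements `fret_means`,
#'   `rate_matrix`, `labels`, `initial_distribution`.
#' @seealso [two_state_model()], [simulate_state_path()],
#'   [stationary_distribution()]
#' @examples
#' m <- two_state_model(0.2, 0.6, dwell1 = 2.51, dwell2 = 2.51)
#' stationary_distribution(m)
#' @export
state_model <- function(fret_means, rate_matrix, labels = NULL,
                        initial_distribution = NULL) {
  fret_means <- as.numeric(fret_means)
  k <- length(fret_means)
  rate_matrix <- as.matrix(rate_matrix)
  if (k < 1L) stop("at least one state is required")
  if (any(fret_means <= 0 | fret_means >= 1))
    stop("fret_means must lie strictly inside (0, 1)")
  if (!all(dim(rate_matrix) == c(k, k)))
    stop("rate_matrix must be ", k, "x", k)
  off <- rate_matrix; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(rate_matrix)) > 1e-8 * (1 + max(abs(rate_matrix)))))
    stop("rate_matrix rows must sum to 0 (non-conservative generator)")
  if (is.null(labels)) labels <- paste0("S", seq_len(k))
  if (is.null(initial_distribution)) {
    initial_distribution <- stationary_from_matrix(rate_matrix)
  }
  initial_distribution <- as.numeric(initial_distribution)
  if (length(initial_distribution) != k || any(initial_distribution < 0) ||
      abs(sum(initial_distribution) - 1) > 1e-9)
    stop("initial_distribution must be a length-", k, " probability vector")
  structure(list(fret_means = fret_means, rate_matrix = rate_matrix,
                 labels = as.character(labels),
                 initial_distribution = initial_distribution),
            class = "state_model")
}

#' @export
print.state_model <- function(x, ...) {
  cat("state_model with", length(x$fret_means), "state(s)\n")
  tab <- data.frame(label = x$labels, fret = x$fret_means,
                    dwell_s = ifelse(diag(x$rate_matrix) < 0,
                                     -1 / diag(x$rate_matrix), Inf),
                    stationary = stationary_distribution(x))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Two-state model from FRET levels and mean dwell times
#'
#' Convenience constructor for the oscillating two-state dynamics seen in
#' dynamic overhang traces: the chain leaves state 1 at rate `1/dwell1` and
#' state 2 at rate `1/dwell2`.
#'
#' @param e1,e2 mean FRET of the two states.
#' @param dwell1,dwell2 mean dwell times (s) of the two states.
#' @inheritParams state_model
#' @return A [state_model()].
#' @export
two_state_model <- function(e1, e2, dwell1, dwell2, labels = NULL) {
  stopifnot(dwell1 > 0, dwell2 > 0)
  r1 <- 1 / dwell1; r2 <- 1 / dwell2
  state_model(c(e1, e2),
              matrix(c(-r1, r1, r2, -r2), 2, 2, byrow = TRUE),
              labels = labels)
}

# Stationary distribution of a conservative rate matrix: the probability
# vector p with p %*% Q = 0, found from the null space of t(Q).
stationary_from_matrix <- function(Q) {
  k <- nrow(Q)
  if (k == 1L) return(1)
  ns <- svd(t(Q))
  v <- ns$u[, which.min(ns$d)]
  p <- abs(v) / sum(abs(v))
  # refine by solving the augmented linear system (guards near-degenerate Q)
  A <- rbind(t(Q), rep(1, k))
  b <- c(rep(0, k), 1)
  fit <- tryCatch(qr.solve(A, b), error = function(e) p)
  if (all(is.finite(fit)) && all(fit > -1e-9)) p <- pmax(fit, 0) / sum(pmax(fit, 0))
  p
}

#' Stationary distribution of a state model
#'
#' @param model a [state_model()].
#' @return numeric probability vector over states.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "state_model"))
  stationary_from_matrix(model$rate_matrix)
}

#' Simulate a continuous-time state path (Gillespie algorithm)
#'
#' Draws a piecewise-constant trajectory from the CTMC of a [state_model()]:
#' the initial state follows `initial_distribution`, holding times are
#' exponential with rate `-Q[i, i]`, and jumps follow the embedded-chain
#' probabilities `Q[i, j] / -Q[i, i]`.
#'
#' @param model a [state_model()].
#' @param duration_s trajectory length in seconds (> 0).
#' @param seed integer seed controlling all randomness.
#' @return A `state_path`: data.frame with columns `state` (integer index) and
#'   `entry_time_s`, plus attributes `duration_s` and `model`. The path covers
#'   `[0, duration_s]`.
#' @examples
#' m <- two_state_model(0.3, 0.7, 1, 1)
#' p <- simulate_state_path(m, 10, seed = 1)
#' @export
simulate_state_path <- function(model, duration_s, seed) {
  stopifnot(inherits(model, "state_model"), duration_s > 0)
  set.seed(as.integer(seed))
  Q <- model$rate_matrix
  k <- nrow(Q)
  s <- sample.int(k, 1, prob = model$initial_distribution)
  states <- integer(0); times <- numeric(0)
  t <- 0
  repeat {
    states <- c(states, s); times <- c(times, t)
    leave <- -Q[s, s]
    if (leave <= 0) break                      # absorbing state
    t <- t + rexp(1, leave)
    if (t >= duration_s) break
    probs <- Q[s, ]; probs[s] <- 0
    s <- sample.int(k, 1, prob = probs)
  }
  structure(data.frame(state = states, entry_time_s = times),
            duration_s = duration_s, model = model, class = c("state_path", "data.frame"))
}

#' Dwell times of a simulated state path
#'
#' @param path a `state_path` from [simulate_state_path()].
#' @param drop_censored drop the final (right-censored) dwell? Default TRUE.
#' @return data.frame with columns `state` and `dwell_s`.
#' @export
path_dwells <- function(path, drop_censored = TRUE) {
  dur <- attr(path, "duration_s")
  ends <- c(path$entry_time_s[-1], dur)
  d <- data.frame(state = path$state, dwell_s = ends - path$entry_time_s)
  if (drop_censored && nrow(d) > 0) d <- d[-nrow(d), , drop = FALSE]
  d
}

#' Time-weighted state occupancy of a state path
#'
#' @param path a `state_path`.
#' @return numeric vector of occupancy fractions per state.
#' @export
path_occupancy <- function(path) {
  model <- attr(path, "model")
  dur <- attr(path, "duration_s")
  k <- length(model$fret_means)
  ends <- c(path$entry_time_s[-1], dur)
  lens <- ends - path$entry_time_s
  occ <- vapply(seq_len(k), function(s) sum(lens[path$state == s]), 0)
  occ / dur
}
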