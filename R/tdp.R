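#' Extract transition records from a fitted HMM path
#'
#' Walks the Viterbi path of an [fit_hmm()]/[select_states()] result:
#' consecutive path segments shorter than `min_dwell_frames` are absorbed
#' into their neighbours (suppressing single-frame shot-noise states;
#' transitions faster than the camera-limited floor are unobservable), and
#' each remaining state boundary emits a record
#' `(e_before, e_after, dwell_before_s)`.
#'
#' The first segment's dwell is left-censored (its entry was not observed);
#' records carry a `censored_before` flag so kinetic fits can drop them.
#'
#' @param fit an `hmm_fit` with a Viterbi path.
#' @param frame_interval_s frame interval; defaults to the fit's.
#' @param min_dwell_frames minimum segment length in frames (default 2).
#' @return data.frame of class `transition_records` with columns `e_before`,
#'   `e_after`, `dwell_before_s`, `censored_before` (no rows for a constant
#'   path).
#' @export
extract_transitions <- function(fit, frame_interval_s = NULL,
                                min_dwell_frames = 2) {
  stopifnot(inherits(fit, "hmm_fit"))
  dt <- if (is.null(frame_interval_s)) fit$frame_interval_s else frame_interval_s
  path <- absorb_short_runs(fit$viterbi_path, min_dwell_frames)
  r <- rle(path)
  empty <- data.frame(e_before = numeric(0), e_after = numeric(0),
                      dwell_before_s = numeric(0), censored_before = logical(0))
  if (length(r$values) < 2L)
    return(structure(empty, class = c("transition_records", "data.frame")))
  nseg <- length(r$values)
  out <- data.frame(
    e_before = fit$means[r$values[-nseg]],
    e_after = fit$means[r$values[-1]],
    dwell_before_s = r$lengths[-nseg] * dt,
    censored_before = c(TRUE, rep(FALSE, nseg - 2L)))
  structure(out, class = c("transition_records", "data.frame"))
}

# Absorb runs shorter than min_len into their longer neighbour, iterating
# until no short run remains (or a single run is left).
absorb_short_runs <- function(path, min_len) {
  if (min_len <= 1L) return(path)
  repeat {
    r <- rle(path)
    n <- length(r$values)
    if (n <= 1L) return(path)
    short <- which(r$lengths < min_len)
    if (length(short) == 0L) return(path)
    i <- short[1]
    left_len <- if (i > 1L) r$lengths[i - 1L] else -1L
    right_len <- if (i < n) r$lengths[i + 1L] else -1L
    r$values[i] <- if (left_len >= right_len) r$values[i - 1L] else r$values[i + 1L]
    path <- inverse.rle(r)
  }
}

#' Pool transitions across traces
#'
#' @param fits list of `hmm_fit` objects.
#' @param ... passed to [extract_transitions()].
#' @return pooled `transition_records`.
#' @export
pool_transitions <- function(fits, ...) {
  recs <- lapply(fits, extract_transitions, ...)
  out <- do.call(rbind, lapply(recs, as.data.frame))
  if (is.null(out)) out <- extract_transitions(fits[[1]], ...)[0, ]
  structure(out, class = c("transition_records", "data.frame"))
}

#' Build a transition density plot (TDP)
#'
#' 2D histogram of `(FRET before, FRET after)` across all detected
#' transitions: ascending transitions (looping) populate the upper-left
#' triangle, descending transitions (unlooping) the lower-right; diagonal
#' bins are empty by construction.
#'
#' @param transitions `transition_records` (>= 1 row).
#' @param bin_width bin width on both axes (default 0.03).
#' @param normalize `"counts"` (default) or `"fraction"` (per-transition
#'   normalization).
#' @return An object of class `tdp_histogram`: list with `counts` (before x
#'   after), `bin_edges`, `mids`, `bin_width`, `n_transitions`.
#' @export
build_tdp <- function(transitions, bin_width = 0.03,
                      normalize = c("counts", "fraction")) {
  normalize <- match.arg(normalize)
  stopifnot(nrow(transitions) >= 1)
  edges <- seq(0, 1 + bin_width / 2, by = bin_width)
  nb <- length(edges) - 1L
  bi <- findInterval(pmin(pmax(transitions$e_before, 0), 1 - 1e-12), edges)
  bj <- findInterval(pmin(pmax(transitions$e_after, 0), 1 - 1e-12), edges)
  M <- matrix(0, nb, nb)
  for (i in seq_along(bi)) M[bi[i], bj[i]] <- M[bi[i], bj[i]] + 1
  if (normalize == "fraction") M <- M / sum(M)
  structure(list(counts = M, bin_edges = edges,
                 mids = edges[-length(edges)] + bin_width / 2,
                 bin_width = bin_width, n_transitions = nrow(transitions)),
            class = "tdp_histogram")
}

#' @export
print.tdp_histogram <- function(x, ...) {
  up <- sum(x$counts[upper.tri(x$counts)])
  lo <- sum(x$counts[lower.tri(x$counts)])
  cat("tdp_histogram:", x$n_transitions, "transitions (",
      up, "ascending /", lo, "descending )\n")
  invisible(x)
}

#' @export
plot.tdp_histogram <- function(x, ...) {
  graphics::image(x$mids, x$mids, x$counts,
                  xlab = "FRET before transition", ylab = "FRET after transition",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  graphics::abline(0, 1, col = "white", lty = 2)
  invisible(x)
}

#' Count distinct FRET levels in a transition density plot
#'
#' 1D mean-shift clustering (Gaussian kernel, bandwidth `bandwidth`) of the
#' pooled transition endpoints `{e_before} U {e_after}`. Discrete states in a
#' TDP are read from its dense spots, so clusters holding less than
#' `min_weight` of the endpoints are treated as sparse noise and not counted.
#'
#' @param transitions `transition_records` (>= `min_transitions` rows) or a
#'   `tdp_histogram` built with [build_tdp()].
#' @param bandwidth mean-shift kernel bandwidth (default 0.07, the state
#'   merge tolerance).
#' @param min_weight minimum endpoint fraction per counted cluster
#'   (default 0.05).
#' @param min_transitions minimum transitions required (default 20).
#' @return list with `n_levels`, `centers` (ascending), `weights`.
#' @export
count_tdp_levels <- function(transitions, bandwidth = 0.07,
                             min_weight = 0.05, min_transitions = 20) {
  if (inherits(transitions, "tdp_histogram")) {
    idx <- which(transitions$counts > 0, arr.ind = TRUE)
    w <- transitions$counts[idx]
    vals <- rep(c(transitions$mids[idx[, 1]], transitions$mids[idx[, 2]]),
                times = c(w, w))
    n_tr <- transitions$n_transitions
  } else {
    vals <- c(transitions$e_before, transitions$e_after)
    n_tr <- nrow(transitions)
  }
  if (n_tr < min_transitions)
    stop("count_tdp_levels requires >= ", min_transitions,
         " transitions (got ", n_tr, ")")
  cl <- mean_shift_1d(vals, bandwidth)
  keep <- cl$weights >= min_weight
  if (!any(keep)) keep[which.max(cl$weights)] <- TRUE
  list(n_levels = sum(keep), centers = cl$centers[keep],
       weights = cl$weights[keep])
}

# 1D mean-shift: iterate each (weight-binned) point to its kernel-weighted
# mode, then group converged modes within bandwidth / 2. Points are pooled
# onto a fine grid first so runtime scales with the grid, not the sample.
mean_shift_1d <- function(x, bandwidth, tol = 1e-6, max_iter = 200,
                          grid = 0.005) {
  g <- round(x / grid) * grid
  tab <- table(g)
  xs <- as.numeric(names(tab))
  ws <- as.numeric(tab)
  # uniform kernel of radius `bandwidth`: only points within the merge
  # tolerance attract, so levels separated by more than it stay distinct
  modes <- vapply(xs, function(m) {
    for (i in seq_len(max_iter)) {
      w <- ws * (abs(xs - m) <= bandwidth)
      m2 <- sum(w * xs) / sum(w)
      if (abs(m2 - m) < tol) break
      m <- m2
    }
    m
  }, 0)
  ord <- order(modes)
  centers <- numeric(0); weights <- numeric(0)
  for (i in ord) {
    m <- modes[i]; wt <- ws[i]
    if (length(centers) && abs(m - centers[length(centers)]) < bandwidth / 2) {
      k <- length(centers)
      centers[k] <- (centers[k] * weights[k] + m * wt) / (weights[k] + wt)
      weights[k] <- weights[k] + wt
    } else {
      centers <- c(centers, m); weights <- c(weights, wt)
    }
  }
  list(centers = centers, weights = weights / sum(ws))
}
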