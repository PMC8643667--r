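#' Convert an intensity trace to a corrected FRET trajectory
#'
#' Per green-excitation frame, background-subtracted intensities give the
#' leakage-corrected ratiometric efficiency
#' `E = (I_A - l * I_D) / (I_A + I_D - l * I_D)`, the standard correction in
#' which the donor-channel crosstalk `l * I_D` is removed from the acceptor
#' channel and from the total. Donor-only molecules map to exactly `E = 0`.
#' The detection-efficiency ratio gamma is fixed at 1 (ratiometric FRET
#' without gamma calibration); it is exposed for completeness.
#'
#' Frames whose corrected total intensity is not positive are masked invalid
#' rather than raising an error. Post-photobleach frames (from
#' [detect_bleach()]) are masked. Raw efficiencies are clipped to
#' `[-0.2, 1.2]` and retained in `raw_efficiency` for diagnostics; the
#' working `efficiency` is clipped to `[0, 1]` for histogramming.
#'
#' @param trace an [intensity_trace()].
#' @param leakage donor-to-acceptor leakage fraction in `[0, 1)`.
#' @param gamma detection-efficiency ratio (default 1).
#' @param background per-channel background counts; `NULL` (default) estimates
#'   it as the mean of dark frames when present, else the 5th percentile of
#'   per-frame total intensity.
#' @param truncate_bleach mask frames at/after a detected photobleach step?
#' @return An object of class `fret_trace`: list with `efficiency` and
#'   `raw_efficiency` (per green frame), `time_s`, `frame_index`,
#'   `valid_mask`, `frame_interval_s`, `leakage_used`, `bleach_frame`, `meta`.
#' @examples
#' tr <- intensity_trace(donor = rep(100, 20), acceptor = rep(100, 20))
#' compute_fret(tr, leakage = 0, background = 0)$efficiency[1]  # 0.5
#' @export
compute_fret <- function(trace, leakage = 0, gamma = 1, background = NULL,
                         truncate_bleach = TRUE) {
  stopifnot(inherits(trace, "intensity_trace"), leakage >= 0, leakage < 1)
  if (is.null(background)) background <- estimate_background(trace)
  g <- which(trace$excitation == "green")
  if (length(g) == 0L) stop("trace has no green-excitation frames")
  d <- trace$donor[g] - background
  a <- trace$acceptor[g] - background
  num <- a - leakage * d
  den <- gamma * d + a - leakage * d
  valid <- den > 0
  raw <- ifelse(valid, num / den, NA_real_)
  raw <- pmin(pmax(raw, -0.2), 1.2)

  bleach <- if (truncate_bleach) detect_bleach(trace, background = background) else NULL
  if (!is.null(bleach)) valid <- valid & g < bleach

  structure(list(efficiency = pmin(pmax(raw, 0), 1),
                 raw_efficiency = raw,
                 frame_index = g,
                 time_s = (g - 1) * trace$frame_interval_s,
                 valid_mask = valid,
                 frame_interval_s = trace$frame_interval_s,
                 leakage_used = leakage,
                 bleach_frame = bleach,
                 meta = trace$meta),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat("fret_trace:", length(x$efficiency), "green frames,",
      sum(x$valid_mask), "valid; leakage", x$leakage_used)
  if (!is.null(x$bleach_frame)) cat("; bleach @ frame", x$bleach_frame)
  cat("\n")
  invisible(x)
}

#' @export
plot.fret_trace <- function(x, ...) {
  graphics::plot(x$time_s, x$efficiency, type = "l", col = "steelblue",
                 xlab = "time (s)", ylab = "FRET efficiency",
                 ylim = c(0, 1), ...)
  if (any(!x$valid_mask))
    graphics::points(x$time_s[!x$valid_mask], x$efficiency[!x$valid_mask],
                     col = "grey", pch = 4, cex = 0.5)
  invisible(x)
}

# Valid efficiencies of a fret_trace (masked frames removed).
valid_efficiency <- function(ft) ft$efficiency[ft$valid_mask]

# Background from dark frames when the ALEX cycle provides them, otherwise
# the 5th percentile of the per-frame per-channel intensity.
estimate_background <- function(trace) {
  dk <- trace$excitation == "dark"
  if (any(dk)) {
    mean(c(trace$donor[dk], trace$acceptor[dk]))
  } else {
    as.numeric(quantile(c(trace$donor, trace$acceptor), 0.05))
  }
}

#' Pooled background estimate across a trace set
#'
#' Mean of the dark-frame intensities pooled over all traces. A single ALEX
#' cycle carries only one dark frame per molecule, so the per-trace estimate
#' is noisy (SE equals the channel noise SD); pooling across an ensemble
#' removes that jitter before [compute_fret()].
#'
#' @param traces a [trace_set()] of [intensity_trace()]s.
#' @return background counts per channel (scalar).
#' @export
ensemble_background <- function(traces) {
  vals <- unlist(lapply(traces, function(tr) {
    dk <- tr$excitation == "dark"
    c(tr$donor[dk], tr$acceptor[dk])
  }))
  if (length(vals) == 0L) {
    mean(vapply(traces, estimate_background, 0))
  } else mean(vals)
}

#' Process a trace set to corrected FRET traces
#'
#' Ensemble-level wrapper around [compute_fret()]: estimates one pooled
#' background with [ensemble_background()] and applies the same leakage to
#' every trace.
#'
#' @param traces a [trace_set()] of [intensity_trace()]s.
#' @param leakage leakage fraction; `NULL` takes each trace's own
#'   `meta$leakage` (simulator ground truth) and 0 when absent.
#' @param background per-channel background; `NULL` pools dark frames.
#' @param ... passed to [compute_fret()].
#' @return list of `fret_trace` objects.
#' @export
process_traces <- function(traces, leakage = NULL, background = NULL, ...) {
  if (is.null(background)) background <- ensemble_background(traces)
  lapply(traces, function(tr) {
    lk <- leakage
    if (is.null(lk)) lk <- if (!is.null(tr$meta$leakage)) tr$meta$leakage else 0
    compute_fret(tr, leakage = lk, background = background, ...)
  })
}

#' Estimate donor leakage from donor-only molecules
#'
#' The leakage coefficient is the value that zeroes the apparent FRET of
#' donor-only molecules: the median of `I_A / I_D` over their
#' background-subtracted green frames.
#'
#' @param donor_only_traces a [trace_set()] (or list) of donor-only
#'   [intensity_trace()]s, e.g. those flagged by [flag_donor_only()].
#' @param background per-channel background; `NULL` estimates per trace.
#' @return estimated leakage fraction.
#' @export
estimate_leakage <- function(donor_only_traces, background = NULL) {
  if (length(donor_only_traces) == 0L)
    stop("estimate_leakage requires at least one donor-only trace")
  ratios <- unlist(lapply(donor_only_traces, function(tr) {
    stopifnot(inherits(tr, "intensity_trace"))
    bg <- if (is.null(background)) estimate_background(tr) else background
    g <- tr$excitation == "green"
    d <- tr$donor[g] - bg
    a <- tr$acceptor[g] - bg
    ok <- d > 0.2 * max(d)   # exclude post-bleach / empty frames
    a[ok] / d[ok]
  }))
  if (length(ratios) == 0L) stop("no usable donor-only frames")
  max(0, median(ratios))
}

#' Flag a molecule as donor-only from its red-excitation frames
#'
#' Under alternating laser excitation, molecules lacking an active acceptor
#' show no signal under direct red excitation. A trace is flagged donor-only
#' when its mean background-subtracted acceptor signal in red frames falls
#' below `threshold_fraction` of the total-intensity reference (the mean
#' background-subtracted green-frame total).
#'
#' @param trace an [intensity_trace()] with at least one red frame.
#' @param threshold_fraction acceptance threshold (default 0.2).
#' @param background per-channel background; `NULL` estimates it.
#' @return logical.
#' @export
flag_donor_only <- function(trace, threshold_fraction = 0.2,
                            background = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  r <- trace$excitation == "red"
  if (!any(r))
    stop("trace has no red-excitation frames; skip ALEX filtering for this data")
  bg <- if (is.null(background)) estimate_background(trace) else background
  red_acc <- mean(trace$acceptor[r]) - bg
  g <- trace$excitation == "green"
  ref <- mean(trace$donor[g] + trace$acceptor[g]) - 2 * bg
  red_acc < threshold_fraction * ref
}

#' Detect single-step photobleaching in an intensity trace
#'
#' Change-point detection on the total green-excitation intensity: the
#' candidate step is the least-squares single change point (the split
#' minimising the summed within-segment sums of squares, equivalent to the
#' extremum of the standardised cumulative-sum statistic at a true step, but
#' with a drift-free location), and a bleach is called when the post-step mean
#' lies within `3 * noise_sd` of the two-channel background and stays there.
#'
#' @param trace an [intensity_trace()].
#' @param background per-channel background; `NULL` estimates it.
#' @param noise_sd channel noise SD; `NULL` estimates it from first
#'   differences of the pre-step segment.
#' @return The first (1-based, whole-trace) frame index of the post-bleach
#'   segment; `0` for an all-background trace; `NULL` if no bleach.
#' @export
detect_bleach <- function(trace, background = NULL, noise_sd = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  g <- which(trace$excitation == "green")
  s <- trace$donor[g] + trace$acceptor[g]
  if (length(s) < 4L) return(NULL)
  bg <- if (is.null(background)) estimate_background(trace) else background
  tot_bg <- 2 * bg
  k <- ls_change_point(s)                            # last pre-step frame
  if (is.na(k)) return(NULL)
  post <- s[(k + 1):length(s)]
  pre <- s[1:k]
  # robust noise from whole-trace first differences: a single bleach step
  # cannot move the median absolute deviation
  nsd <- if (is.null(noise_sd)) {
    v <- stats::mad(diff(s)) / sqrt(2)
    if (is.finite(v) && v > 0) v else 1e-9
  } else max(noise_sd, 1e-9)
  thr <- tot_bg + 3 * sqrt(2) * nsd                  # background band (total)
  pre_dark <- mean(pre) <= thr
  post_dark <- mean(post) <= thr && all(post <= tot_bg + 5 * sqrt(2) * nsd)
  if (pre_dark && mean(s) <= thr) return(0L)         # all-background trace
  if (!pre_dark && post_dark) return(g[k + 1])
  NULL
}
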