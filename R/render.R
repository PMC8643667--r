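#' Camera and dye photophysics parameters
#'
#' Parameters of the emission model used by [render_trace()]: a constant total
#' emission rate split between donor and acceptor channels by the
#' frame-averaged FRET efficiency, additive Gaussian per-channel read noise
#' (the standard EMCCD approximation), donor->acceptor spectral leakage,
#' single-step photobleaching, and a constant per-channel background.
#'
#' The channel model per green frame with frame-averaged efficiency `E` is
#' `donor = (1 - E) * total_intensity` and
#' `acceptor = E * total_intensity + leakage * donor` (leakage expressed as a
#' fraction of the detected donor signal, the convention under which the
#' ratiometric correction of [compute_fret()] is its exact inverse), plus
#' background and noise in each channel.
#'
#' @param total_intensity mean total counts/frame (> 0). Default 1000.
#' @param noise_sd per-channel additive Gaussian noise SD in counts. Default
#'   `total_intensity / 12`.
#' @param leakage donor-to-acceptor leakage fraction in `[0, 1)`. Default 0.08.
#' @param gamma detection-efficiency ratio; fixed at 1 throughout the
#'   analysis and kept only for completeness.
#' @param donor_bleach_rate,acceptor_bleach_rate per-second single-step
#'   photobleaching rates (>= 0, default 0: bleaching off).
#' @param background constant per-channel background counts/frame. Default 50.
#' @return An object of class `photophysics`.
#' @export
photophysics <- function(total_intensity = 1000,
                         noise_sd = total_intensity / 12,
                         leakage = 0.08, gamma = 1,
                         donor_bleach_rate = 0, acceptor_bleach_rate = 0,
                         background = 50) {
  stopifnot(total_intensity > 0, noise_sd >= 0,
            leakage >= 0, leakage < 1, gamma > 0,
            donor_bleach_rate >= 0, acceptor_bleach_rate >= 0,
            background >= 0)
  structure(list(total_intensity = total_intensity, noise_sd = noise_sd,
                 leakage = leakage, gamma = gamma,
                 donor_bleach_rate = donor_bleach_rate,
                 acceptor_bleach_rate = acceptor_bleach_rate,
                 background = background),
            class = "photophysics")
}

#' Alternating laser excitation (ALEX) scheme
#'
#' Frame-level excitation pattern: a block of green (donor-excitation) frames,
#' dark frames, then red (direct acceptor excitation) frames. With
#' `repeat_cycle = TRUE` the cycle repeats for the whole movie (short
#' histogram movies); with `FALSE` a single leading ALEX block is followed by
#' continuous green excitation (long kinetic movies, where the red block
#' serves only to flag acceptor-less molecules).
#'
#' @param green_frames,dark_frames,red_frames frame counts per cycle
#'   (>= 0; at least one green frame).
#' @param repeat_cycle logical; repeat the cycle for the whole trace?
#' @return An object of class `excitation_scheme`.
#' @export
excitation_scheme <- function(green_frames = 10, dark_frames = 1,
                              red_frames = 10, repeat_cycle = FALSE) {
  stopifnot(green_frames >= 1, dark_frames >= 0, red_frames >= 0)
  structure(list(green_frames = green_frames, dark_frames = dark_frames,
                 red_frames = red_frames, repeat_cycle = repeat_cycle),
            class = "excitation_scheme")
}

#' Per-frame excitation labels for a scheme
#'
#' @param scheme an [excitation_scheme()].
#' @param n_frames number of frames.
#' @return character vector of labels in `{"green", "dark", "red"}`.
#' @export
excitation_labels <- function(scheme, n_frames) {
  stopifnot(inherits(scheme, "excitation_scheme"), n_frames >= 1)
  cyc <- c(rep("green", scheme$green_frames), rep("dark", scheme$dark_frames),
           rep("red", scheme$red_frames))
  if (scheme$repeat_cycle) {
    rep(cyc, length.out = n_frames)
  } else {
    c(cyc, rep("green", max(0L, n_frames - length(cyc))))[seq_len(n_frames)]
  }
}

#' Construct a per-molecule intensity trace
#'
#' The pipeline's input container: per-frame donor and acceptor counts at a
#' fixed frame interval, with per-frame excitation labels and free-form
#' metadata (construct label, protein condition, flow frame, seed provenance).
#'
#' @param donor,acceptor numeric count vectors of equal length (>= 0 up to
#'   noise; negative values from read noise are permitted).
#' @param excitation per-frame labels in `{"green", "dark", "red"}`.
#' @param frame_interval_s frame interval in seconds (> 0). Default 0.1.
#' @param meta named list of metadata.
#' @return An object of class `intensity_trace`.
#' @export
intensity_trace <- function(donor, acceptor, excitation = NULL,
                            frame_interval_s = 0.1, meta = list()) {
  n <- length(donor)
  if (is.null(excitation)) excitation <- rep("green", n)
  stopifnot(length(acceptor) == n, length(excitation) == n,
            frame_interval_s > 0,
            all(excitation %in% c("green", "dark", "red")))
  structure(list(donor = as.numeric(donor), acceptor = as.numeric(acceptor),
                 excitation = as.character(excitation),
                 frame_interval_s = frame_interval_s, meta = meta),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat("intensity_trace:", length(x$donor), "frames @",
      x$frame_interval_s, "s/frame;",
      sum(x$excitation == "green"), "green frames\n")
  if (length(x$meta)) {
    keys <- names(x$meta)
    cat("  meta:", paste(keys, unlist(lapply(x$meta, function(v)
      paste(format(v), collapse = ","))), sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
plot.intensity_trace <- function(x, ...) {
  t <- (seq_along(x$donor) - 1) * x$frame_interval_s
  graphics::plot(t, x$donor, type = "l", col = "darkgreen",
                 xlab = "time (s)", ylab = "counts",
                 ylim = range(c(x$donor, x$acceptor)), ...)
  graphics::lines(t, x$acceptor, col = "red")
  invisible(x)
}

#' Bundle traces into a trace set
#'
#' @param traces list of [intensity_trace()] (or [compute_fret()] results).
#' @return An object of class `trace_set` (a list with class attribute).
#' @export
trace_set <- function(traces) {
  stopifnot(is.list(traces))
  structure(traces, class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("trace_set of", length(x), "traces\n")
  labs <- unlist(lapply(x, function(tr) {
    if (!is.null(tr$meta$label)) tr$meta$label else NA_character_
  }))
  if (any(!is.na(labs))) print(table(labs, useNA = "no"))
  invisible(x)
}

#' @export
`[.trace_set` <- function(x, i) trace_set(unclass(x)[i])

# Frame-averaged FRET means: time-weight the state means of `path` within
# each camera frame window [f*dt, (f+1)*dt). Camera blurring of fast
# transitions is reproduced by construction.
frame_average_fret <- function(path, n_frames, frame_interval_s) {
  model <- attr(path, "model")
  starts <- path$entry_time_s
  ends <- c(starts[-1], max(attr(path, "duration_s"), n_frames * frame_interval_s))
  evals <- model$fret_means[path$state]
  acc <- numeric(n_frames)
  fb <- (seq_len(n_frames) - 1) * frame_interval_s   # frame starts
  fe <- fb + frame_interval_s
  for (i in seq_along(starts)) {
    f0 <- max(1L, 1L + floor(starts[i] / frame_interval_s + 1e-12))
    f1 <- min(n_frames, 1L + ceiling(ends[i] / frame_interval_s - 1e-12) - 1L)
    if (f0 > f1) next
    idx <- f0:f1
    ov <- pmin(fe[idx], ends[i]) - pmax(fb[idx], starts[i])
    acc[idx] <- acc[idx] + pmax(ov, 0) * evals[i]
  }
  acc / frame_interval_s
}

#' Render an intensity trace from a state path
#'
#' Converts a continuous-time state path into camera frames: per green frame
#' the frame-averaged FRET efficiency is computed by time-weighting state
#' means within the frame window, then split into donor/acceptor counts under
#' the [photophysics()] emission model. Dark frames carry background only; red
#' frames report direct acceptor excitation (near-background once the acceptor
#' has bleached). Photobleaching is single-step: after a drawn donor bleach
#' time both channels fall to background; after acceptor bleach the acceptor
#' falls to background while the donor rises to the full total intensity.
#'
#' @param path a `state_path` from [simulate_state_path()].
#' @param phys a [photophysics()] object.
#' @param scheme an [excitation_scheme()].
#' @param n_frames number of camera frames.
#' @param seed integer seed.
#' @param frame_interval_s frame interval in seconds. Default 0.1.
#' @param meta extra metadata stored on the trace.
#' @return An [intensity_trace()]. Ground truth (frame-averaged FRET, bleach
#'   frames, seed) is stored in `meta` for recovery tests.
#' @export
render_trace <- function(path, phys = photophysics(),
                         scheme = excitation_scheme(), n_frames,
                         seed, frame_interval_s = 0.1, meta = list()) {
  stopifnot(inherits(phys, "photophysics"), n_frames > 0)
  set.seed(as.integer(seed))
  exc <- excitation_labels(scheme, n_frames)
  efret <- frame_average_fret(path, n_frames, frame_interval_s)

  t_end <- n_frames * frame_interval_s
  d_bleach <- if (phys$donor_bleach_rate > 0) rexp(1, phys$donor_bleach_rate) else Inf
  a_bleach <- if (phys$acceptor_bleach_rate > 0) rexp(1, phys$acceptor_bleach_rate) else Inf
  d_bleach_fr <- if (d_bleach < t_end) 1L + floor(d_bleach / frame_interval_s) else NA_integer_
  a_bleach_fr <- if (a_bleach < t_end) 1L + floor(a_bleach / frame_interval_s) else NA_integer_

  fr <- seq_len(n_frames)
  donor_alive <- is.na(d_bleach_fr) | fr < d_bleach_fr
  acc_alive <- is.na(a_bleach_fr) | fr < a_bleach_fr

  T0 <- phys$total_intensity
  E <- ifelse(acc_alive, efret, 0)          # no transfer once acceptor is dark
  donor <- numeric(n_frames); acceptor <- numeric(n_frames)

  g <- exc == "green"
  dn <- (1 - E) * T0
  donor[g] <- ifelse(donor_alive[g], dn[g], 0)
  acceptor[g] <- ifelse(donor_alive[g], E[g] * T0 + phys$leakage * dn[g], 0)

  r <- exc == "red"
  acceptor[r] <- ifelse(acc_alive[r], T0, 0)
  donor[r] <- 0
  # dark frames: both channels stay at background

  donor <- donor + phys$background
  acceptor <- acceptor + phys$background
  if (phys$noise_sd > 0) {
    donor <- donor + rnorm(n_frames, 0, phys$noise_sd)
    acceptor <- acceptor + rnorm(n_frames, 0, phys$noise_sd)
  }

  meta <- modifyList(list(seed = seed,
                          true_fret = efret,
                          donor_bleach_frame = d_bleach_fr,
                          acceptor_bleach_frame = a_bleach_fr,
                          leakage = phys$leakage,
                          total_intensity = T0,
                          noise_sd = phys$noise_sd,
                          background = phys$background), meta)
  intensity_trace(donor, acceptor, exc, frame_interval_s, meta)
}
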