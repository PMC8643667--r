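#' Extract dwell times from classified traces
#'
#' In `excursion_duration` mode (the default, used for the Dynamic-I/II dwell
#' analysis) the dwell is the duration between excursion entry and exit as
#' detected by [classify_trace()]. Excursions still in progress when the
#' trace ends are right-censored: their observed durations are returned in
#' the `censored_s` attribute so [fit_exponential()] can count them as
#' exposure (long dwells are length-biased towards hitting the trace end;
#' silently dropping them clips the tail of the dwell distribution).
#' Excursions already in progress at the first frame exit within the trace,
#' and by the memorylessness of the exponential their observed residual
#' durations are complete draws, so they are kept as ordinary events. In
#' `hmm_state_dwell` mode dwells come from [extract_transitions()] of
#' per-trace HMM fits (uncensored `dwell_before_s` values).
#'
#' @param traces `fret_trace` objects.
#' @param classes matching list of `trace_class` objects (from
#'   [classify_traces()]); computed on the fly when `NULL`.
#' @param class_filter keep dwells only from traces with these labels
#'   (default all dynamic labels).
#' @param event_definition `"excursion_duration"` or `"hmm_state_dwell"`.
#' @param hmm_fits for `hmm_state_dwell`, matching list of `hmm_fit`s.
#' @param ... passed to [classify_trace()] when classes are computed here.
#' @return numeric vector of complete dwell times (seconds), possibly empty,
#'   with right-censored observed durations in `attr(, "censored_s")`.
#' @export
extract_dwells <- function(traces, classes = NULL,
                           class_filter = c("dynamicI", "dynamicII",
                                            "dynamicI_II"),
                           event_definition = c("excursion_duration",
                                                "hmm_state_dwell"),
                           hmm_fits = NULL, ...) {
  event_definition <- match.arg(event_definition)
  if (is.null(classes)) classes <- classify_traces(traces, ...)
  keep <- vapply(classes, function(cl) cl$label %in% class_filter, TRUE)
  censored <- numeric(0)
  if (event_definition == "excursion_duration") {
    n_valid <- vapply(traces, function(ft) sum(ft$valid_mask), 0L)
    dwells <- unlist(lapply(which(keep), function(i) {
      ex <- classes[[i]]$excursions
      open_end <- ex$end == n_valid[i]
      censored <<- c(censored, ex$dwell_s[open_end])
      ex$dwell_s[!open_end]
    }))
  } else {
    if (is.null(hmm_fits)) stop("hmm_state_dwell mode requires hmm_fits")
    dwells <- unlist(lapply(which(keep), function(i) {
      tr <- extract_transitions(hmm_fits[[i]])
      tr$dwell_before_s[!tr$censored_before]
    }))
  }
  dwells <- if (is.null(dwells)) numeric(0) else as.numeric(dwells)
  attr(dwells, "censored_s") <- censored
  attr(dwells, "frame_s") <- if (length(traces))
    traces[[1]]$frame_interval_s else 0
  dwells
}

#' Single-exponential fit of dwell times
#'
#' Default method is the unbinned maximum-likelihood estimator with
#' left-truncation at the detection floor: for an exponential observed only
#' above `floor_s`, `tau = mean(d - floor_s)` over dwells `d >= floor_s` is
#' the exact MLE, removing the upward bias that an uncorrected mean acquires
#' when short events fall below the camera-limited floor. When the dwells
#' are frame-quantized (`frame_s > 0`, set automatically by
#' [extract_dwells()]) the estimator switches to the matching geometric MLE
#' `tau = -frame_s / log(S / (S + n))` (with `S` the summed excess over the
#' floor in frames and `n` the complete-event count): camera discretization
#' makes frame counts geometric rather than exponential, and the continuous
#' formula is biased low by about half a frame. Right-censored events
#' contribute exposure to `S` but not to `n`. The binned least-squares fit
#' of `A * exp(-t / tau)` to the dwell histogram (the conventional
#' plot-and-fit approach) is retained as `method = "binned_lsq"`.
#' Confidence intervals are nonparametric bootstrap.
#'
#' @param dwells numeric dwell times (s); >= 10 events required.
#' @param method `"mle"` (default) or `"binned_lsq"`.
#' @param floor_s left-truncation point (default 0.3 s: one frame above the
#'   2-frame detection floor, so that short events smeared onto the floor
#'   by camera discretization do not pile up at the truncation point; set 0
#'   to disable truncation handling).
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed bootstrap seed.
#' @param bin_width_s bin width for `binned_lsq` (default 0.2 s).
#' @param censored_s observed durations of right-censored events (default:
#'   the `censored_s` attribute of `dwells`, as set by [extract_dwells()]).
#'   Under `"mle"` they contribute exposure but no event count, the standard
#'   survival-analysis treatment; ignored by `"binned_lsq"`.
#' @param frame_s frame quantum of the dwell values (default: the `frame_s`
#'   attribute of `dwells`, else 0 = continuous-time MLE).
#' @return An object of class `dwell_fit`: list with `tau_s`, `ci95`,
#'   `n_events`, `n_censored`, `method`, `floor_s`, `frame_s`, `degenerate`
#'   (zero-spread sample flag).
#' @export
fit_exponential <- function(dwells, method = c("mle", "binned_lsq"),
                            floor_s = 0.3, n_boot = 1000, seed = 1,
                            bin_width_s = 0.2,
                            censored_s = attr(dwells, "censored_s"),
                            frame_s = attr(dwells, "frame_s")) {
  method <- match.arg(method)
  if (is.null(censored_s)) censored_s <- numeric(0)
  if (is.null(frame_s)) frame_s <- 0
  censored_s <- as.numeric(censored_s)
  dwells <- as.numeric(dwells)
  if (length(dwells) < 10L)
    stop("fit_exponential requires >= 10 events (got ", length(dwells), ")")

  est <- function(d, cens = censored_s) {
    if (method == "mle") {
      cens <- cens[cens >= floor_s]
      d <- d[d >= floor_s]
      if (length(d) == 0L) return(NA_real_)
      expo <- sum(d - floor_s) + sum(cens - floor_s)
      n <- length(d)
      if (frame_s > 0 && expo > 0) {
        S <- expo / frame_s
        -frame_s / log(S / (S + n))
      } else {
        expo / n
      }
    } else {
      h <- graphics::hist(d, breaks = seq(0, max(d) + bin_width_s, bin_width_s),
                          plot = FALSE)
      use <- h$counts > 0 & h$mids >= floor_s
      if (sum(use) < 2L) return(mean(d[d >= floor_s]) - floor_s)
      fit <- tryCatch(
        minpack.lm::nlsLM(counts ~ A * exp(-mids / tau),
                          data = data.frame(counts = h$counts[use],
                                            mids = h$mids[use]),
                          start = list(A = max(h$counts), tau = max(mean(d), 0.1))),
        error = function(e) NULL)
      if (is.null(fit)) mean(d[d >= floor_s]) - floor_s else coef(fit)[["tau"]]
    }
  }
  tau <- est(dwells)
  if (!is.finite(tau) || tau <= 0)
    stop("exponential fit failed (tau = ", tau, ")")
  degenerate <- sd(dwells) == 0
  if (degenerate && method == "mle" && floor_s > 0) tau <- mean(dwells)

  set.seed(as.integer(seed))
  all_d <- c(dwells, censored_s)
  is_cens <- c(rep(FALSE, length(dwells)), rep(TRUE, length(censored_s)))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(all_d), replace = TRUE)
    if (degenerate) mean(all_d[idx]) else est(all_d[idx][!is_cens[idx]],
                                              all_d[idx][is_cens[idx]])
  }, 0)
  ci <- as.numeric(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  structure(list(tau_s = tau, ci95 = ci, n_events = length(dwells),
                 n_censored = length(censored_s),
                 method = method, floor_s = floor_s, frame_s = frame_s,
                 degenerate = degenerate),
            class = "dwell_fit")
}

#' @export
print.dwell_fit <- function(x, ...) {
  cat(sprintf("dwell_fit (%s): tau = %.3f s [%.3f, %.3f], n = %d%s\n",
              x$method, x$tau_s, x$ci95[1], x$ci95[2], x$n_events,
              if (x$degenerate) " (degenerate: zero spread)" else ""))
  invisible(x)
}

#' Time from flow to first irreversible binding
#'
#' The binding time of a real-time flow trace: the first frame after the
#' moment of flow where the efficiency crosses `midpoint` towards the bound
#' level and remains there for at least `persist_frames` frames (the
#' "irreversible" criterion; transient dips recover and are not counted).
#'
#' @param flow_trace a `fret_trace` of a flow experiment.
#' @param flow_frame 1-based whole-trace frame index of the flow moment
#'   (defaults to `meta$flow_frame`).
#' @param midpoint bound/unbound FRET midpoint (default 0.475, between the
#'   free-G4 0.65 and POT1-bound 0.3 levels).
#' @param direction `"down"` (binding lowers FRET, default) or `"up"`.
#' @param persist_frames persistence window (default 10 frames = 1 s).
#' @return seconds from flow to binding, or `NA` if never.
#' @export
time_to_first_binding <- function(flow_trace, flow_frame = NULL,
                                  midpoint = 0.475,
                                  direction = c("down", "up"),
                                  persist_frames = 10) {
  direction <- match.arg(direction)
  stopifnot(inherits(flow_trace, "fret_trace"))
  if (is.null(flow_frame)) flow_frame <- flow_trace$meta$flow_frame
  if (is.null(flow_frame)) stop("flow_frame is required")
  e <- flow_trace$efficiency
  g <- flow_trace$frame_index
  past <- which(g > flow_frame & flow_trace$valid_mask)
  if (length(past) == 0L) return(NA_real_)
  bound <- if (direction == "down") e < midpoint else e > midpoint
  run <- 0L
  for (i in past) {
    run <- if (bound[i]) run + 1L else 0L
    if (run >= persist_frames) {
      first <- i - persist_frames + 1L
      return((g[first] - flow_frame) * flow_trace$frame_interval_s)
    }
  }
  # bound to the end of the movie also counts as irreversible
  if (run > 0L) {
    first <- past[length(past)] - run + 1L
    if (first >= past[1])
      return((g[first] - flow_frame) * flow_trace$frame_interval_s)
  }
  NA_real_
}

#' Observed binding rate from a bound-fraction time course
#'
#' Fits the exponential saturation `f(t) = f_max * (1 - exp(-k_obs * t))` to
#' bound fractions measured over time (histogram snapshots at low
#' concentration). A time course already saturated at t = 0 is flagged
#' out-of-range (`k_obs = Inf`).
#'
#' @param time_s times (>= 4 points).
#' @param fraction bound fractions at those times.
#' @param f_max_fixed optionally fix the plateau.
#' @return list with `k_obs`, `f_max`, `ci95` (on `k_obs`), `fit` (the nls
#'   object) — or `k_obs = Inf` with `out_of_range = TRUE` for degenerate
#'   input.
#' @export
bound_fraction_timecourse <- function(time_s, fraction, f_max_fixed = NULL) {
  stopifnot(length(time_s) == length(fraction), length(time_s) >= 4)
  if (all(fraction >= 0.99 * max(1e-12, max(fraction))) && fraction[1] > 0.9)
    return(list(k_obs = Inf, f_max = max(fraction), ci95 = c(NA, NA),
                fit = NULL, out_of_range = TRUE))
  df <- data.frame(t = time_s, f = fraction)
  k0 <- {
    early <- df[df$f < 0.8 * max(df$f) & df$t > 0, ]
    if (nrow(early) > 0) max(df$f[which.max(df$t)], 0.5) /
      max(mean(early$t), 1e-6) else 1 / max(df$t)
  }
  fit <- tryCatch({
    if (is.null(f_max_fixed)) {
      minpack.lm::nlsLM(f ~ fmax * (1 - exp(-k * t)), data = df,
                        start = list(fmax = max(df$f), k = min(k0, 10)),
                        lower = c(1e-6, 1e-9), upper = c(1.5, 1e3))
    } else {
      minpack.lm::nlsLM(f ~ f_max_fixed * (1 - exp(-k * t)), data = df,
                        start = list(k = min(k0, 10)),
                        lower = 1e-9, upper = 1e3)
    }
  }, error = function(e) stop("time-course fit failed to converge: ",
                              conditionMessage(e)))
  co <- coef(fit)
  k <- co[["k"]]
  se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                 error = function(e) NA_real_)
  list(k_obs = k,
       f_max = if (is.null(f_max_fixed)) co[["fmax"]] else f_max_fixed,
       ci95 = k + c(-1.96, 1.96) * se, fit = fit, out_of_range = FALSE)
}

#' Association rate constant from a concentration series
#'
#' Least-squares line through the origin of observed rate versus
#' concentration (`k_obs = kon * c`; with no observable dissociation the
#' intercept is zero). The free-intercept variant is reported alongside.
#'
#' @param concentrations_nM concentrations (>= 3).
#' @param k_obs observed rates (per s).
#' @return list with `kon_per_nM_per_s` (origin-constrained slope),
#'   `kon_free_intercept`, `intercept`.
#' @export
fit_kon <- function(concentrations_nM, k_obs) {
  stopifnot(length(concentrations_nM) == length(k_obs),
            length(concentrations_nM) >= 3)
  slope0 <- sum(concentrations_nM * k_obs) / sum(concentrations_nM^2)
  fi <- lm(k_obs ~ concentrations_nM)
  list(kon_per_nM_per_s = slope0,
       kon_free_intercept = unname(coef(fi)[2]),
       intercept = unname(coef(fi)[1]))
}

#' Apparent dissociation constant from equilibrium bound fractions
#'
#' Least-squares fit of the Langmuir isotherm `f = c / (c + K_D)` to
#' equilibrium bound fractions across a concentration titration; the
#' half-saturation concentration is the apparent K_D.
#'
#' @param concentrations_nM concentrations (>= 4, spanning the transition).
#' @param fractions equilibrium bound fractions.
#' @param n_boot,seed bootstrap resamples over concentration points for the
#'   CI (0 disables).
#' @return An object of class `binding_assay`: list with `kd_app_nM`, `ci95`,
#'   `fit`, `concentrations_nM`, `fractions`.
#' @export
estimate_kd_app <- function(concentrations_nM, fractions, n_boot = 200,
                            seed = 1) {
  stopifnot(length(concentrations_nM) == length(fractions),
            length(concentrations_nM) >= 4)
  if (all(fractions < 0.05) || all(fractions > 0.95))
    stop("bound fractions do not span the transition; K_D unidentifiable")
  df <- data.frame(c = concentrations_nM, f = fractions)
  fit_one <- function(d) {
    half <- tryCatch(approx(d$f, d$c, xout = 0.5, ties = mean)$y,
                     error = function(e) NA_real_)
    k0 <- if (is.finite(half) && half > 0) half else median(d$c)
    fit <- minpack.lm::nlsLM(f ~ c / (c + kd), data = d,
                             start = list(kd = k0),
                             lower = 1e-6, upper = 1e6)
    coef(fit)[["kd"]]
  }
  kd <- fit_one(df)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boot <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(nrow(df), replace = TRUE)
      tryCatch(fit_one(df[idx, ]), error = function(e) NA_real_)
    }, 0)
    ci <- as.numeric(quantile(boot, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(kd_app_nM = kd, ci95 = ci, concentrations_nM = concentrations_nM,
                 fractions = fractions),
            class = "binding_assay")
}

#' @export
print.binding_assay <- function(x, ...) {
  cat(sprintf("binding_assay: K_D-app = %.3g nM [%.3g, %.3g]\n",
              x$kd_app_nM, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Detect a PIFE intensity-enhancement step
#'
#' Protein-induced fluorescence enhancement is a FRET-independent upward step
#' in total intensity at the binding moment. A change-point on the total
#' green-frame intensity after the flow moment is accepted when the
#' post-step/pre-step mean ratio is at least `min_enhancement`.
#'
#' @param trace an [intensity_trace()].
#' @param flow_frame 1-based flow frame (defaults to `meta$flow_frame`).
#' @param min_enhancement minimum accepted enhancement (default 1.2).
#' @param background per-channel background; `NULL` estimates it.
#' @return An object of class `pife_event` (list with `step_frame`,
#'   `enhancement_factor`, `time_from_flow_s`) or `NULL` when no step is
#'   found.
#' @export
detect_pife <- function(trace, flow_frame = NULL, min_enhancement = 1.2,
                        background = NULL) {
  stopifnot(inherits(trace, "intensity_trace"))
  if (is.null(flow_frame)) flow_frame <- trace$meta$flow_frame
  if (is.null(flow_frame)) stop("flow_frame is required")
  bg <- if (is.null(background)) estimate_background(trace) else background
  g <- which(trace$excitation == "green" & seq_along(trace$donor) >= flow_frame)
  if (length(g) < 4L) return(NULL)
  s <- trace$donor[g] + trace$acceptor[g] - 2 * bg
  k <- ls_change_point(s)                 # last pre-step frame
  if (is.na(k) || k < 1L || k >= length(s)) return(NULL)
  pre <- mean(s[1:k]); post <- mean(s[(k + 1):length(s)])
  if (pre <= 0 || post <= pre || post / pre < min_enhancement) return(NULL)
  step_frame <- g[k + 1L]
  structure(list(step_frame = step_frame,
                 enhancement_factor = post / pre,
                 time_from_flow_s = (step_frame - flow_frame) *
                   trace$frame_interval_s),
            class = "pife_event")
}

# Least-squares single change point: k minimising the summed within-segment
# sums of squares of s[1:k] and s[(k+1):n]; robust to the step position,
# unlike cusum extrema whose location drifts under weak post-step drift.
ls_change_point <- function(s) {
  n <- length(s)
  if (n < 4L) return(NA_integer_)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  k <- seq_len(n - 1L)
  sse_left <- cs2[k] - cs[k]^2 / k
  sse_right <- (cs2[n] - cs2[k]) - (cs[n] - cs[k])^2 / (n - k)
  which.min(sse_left + sse_right)
}

#' @export
print.pife_event <- function(x, ...) {
  cat(sprintf("pife_event: step at frame %d (%.2fx, %.2f s after flow)\n",
              x$step_frame, x$enhancement_factor, x$time_from_flow_s))
  invisible(x)
}

#' Ensemble PIFE binding rate
#'
#' Detects PIFE steps across flow traces and fits the waiting times
#' (flow to step) with a single exponential; the binding rate is `1 / tau`.
#'
#' @param traces [intensity_trace()]s from a PIFE flow assay.
#' @param ... passed to [detect_pife()].
#' @param floor_s truncation floor for the waiting-time fit (default 0,
#'   the step detector needs no minimum dwell).
#' @param seed bootstrap seed for the exponential fit.
#' @return list with `rate_per_s`, `ci95`, `n_events`, `waiting_times_s`.
#' @export
pife_binding_rate <- function(traces, ..., floor_s = 0, seed = 1) {
  waits <- unlist(lapply(traces, function(tr) {
    ev <- detect_pife(tr, ...)
    if (is.null(ev)) NA_real_ else ev$time_from_flow_s
  }))
  waits <- waits[!is.na(waits) & waits > 0]
  fit <- fit_exponential(waits, method = "mle", floor_s = floor_s, seed = seed)
  list(rate_per_s = 1 / fit$tau_s, ci95 = rev(1 / fit$ci95),
       n_events = fit$n_events, waiting_times_s = waits)
}
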