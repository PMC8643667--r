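# Registry of named simulation presets encoding the experimental scenarios:
# DNA constructs (2R/4R overhangs, telomeric duplex valency), protein
# conditions (free G4, POT1-bound steady and dynamic classes, TRF2 ladder),
# flow-injection binding assays, and ensemble mixtures. Defaults are the
# study conditions; see the methods vignette for the provenance of each
# number.

preset_registry <- function() {
  list(
    # single-state equilibrium conditions
    G4_free = function() list(
      model = state_model(0.65, matrix(0, 1, 1), labels = "G4"),
      phys = photophysics()),
    POT1_steady_4R = function() list(
      model = state_model(0.30, matrix(0, 1, 1), labels = "POT1_bound"),
      phys = photophysics()),
    free_2R = function() list(
      model = state_model(0.80, matrix(0, 1, 1), labels = "free_2R"),
      phys = photophysics()),
    POT1_steady_2R = function() list(
      model = state_model(0.60, matrix(0, 1, 1), labels = "POT1_2R_bound"),
      phys = photophysics()),
    # dynamic classes: slow oscillation (Dynamic-I), sharp high-FRET spikes
    # (Dynamic-II), and the monomer-POT1 2R oscillation
    POT1_dynamicI = function() list(
      model = two_state_model(0.2, 0.55, dwell1 = 2.51, dwell2 = 2.51,
                              labels = c("low", "high")),
      phys = photophysics()),
    POT1_dynamicII = function() list(
      model = two_state_model(0.25, 0.85, dwell1 = 3.0, dwell2 = 0.63,
                              labels = c("baseline", "spike")),
      phys = photophysics()),
    POT1_2R = function() list(
      model = two_state_model(0.6, 0.3, dwell1 = 2.31, dwell2 = 2.31,
                              labels = c("bound", "extended")),
      phys = photophysics()),
    # TRF2 + POT1 stepwise looping ladders. Four TRF2 units on the 4-repeat
    # duplex give four looped levels (0.35/0.55/0.70/0.85) walked by
    # nearest-neighbour steps, plus a rarely visited unlooped ~0.2 level.
    TRF2_POT1_4R_ladder = function() list(
      model = ladder_model(c(0.35, 0.55, 0.70, 0.85), dwell = 0.8,
                           unlooped = 0.2, unlooped_entry_rate = 0.01,
                           unlooped_dwell = 0.8),
      phys = photophysics()),
    TRF2_POT1_2Rduplex = function() list(
      model = two_state_model(0.55, 0.80, dwell1 = 0.8, dwell2 = 0.8,
                              labels = c("loop1", "loop2")),
      phys = photophysics()),
    # flow-injection assays
    flow_TRF2_PIFE = function() list(
      model = state_model(0.65, matrix(0, 1, 1)),
      phys = photophysics(),
      flow = flow_assay_design(concentration_nM = 1,
                               kon_per_nM_per_s = 0.13,
                               flow_time_s = 10,
                               pre_binding_model = state_model(0.65, matrix(0, 1, 1)),
                               post_binding_model = state_model(0.65, matrix(0, 1, 1)),
                               pife_enhancement = 1.4)),
    # ensemble mixtures of steady/Dynamic-I/Dynamic-II populations
    POT1_only = function() list(
      mixture = c(POT1_steady_4R = 0.40, POT1_dynamicI = 0.35,
                  POT1_dynamicII = 0.25)),
    POT1_TRF2 = function() list(
      mixture = c(POT1_steady_4R = 0.20, POT1_dynamicI = 0.45,
                  POT1_dynamicII = 0.35))
  )
}

# Nearest-neighbour ladder CTMC over `levels`, each with mean dwell `dwell`,
# plus an optional rarely visited unlooped state reachable from the lowest
# looped level.
ladder_model <- function(levels, dwell, unlooped = NULL,
                         unlooped_entry_rate = 0, unlooped_dwell = 1) {
  k <- length(levels)
  Q <- matrix(0, k, k)
  leave <- 1 / dwell
  for (i in seq_len(k)) {
    nb <- c(i - 1, i + 1); nb <- nb[nb >= 1 & nb <= k]
    Q[i, nb] <- leave / length(nb)
  }
  if (!is.null(unlooped)) {
    Q <- rbind(cbind(Q, 0), 0)
    k2 <- k + 1
    Q[1, k2] <- unlooped_entry_rate
    Q[k2, 1] <- 1 / unlooped_dwell
    levels <- c(levels, unlooped)
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  ord <- order(levels)
  state_model(levels[ord], Q[ord, ord, drop = FALSE])
}

#' Flow-injection binding assay design
#'
#' Describes a real-time flow experiment: the molecule follows
#' `pre_binding_model` until a protein-binding time drawn as an exponential
#' waiting time with rate `kon_per_nM_per_s * concentration_nM` after the
#' moment of flow, then switches to `post_binding_model`. The PIFE variant
#' instead multiplies both channel intensities by `pife_enhancement` at the
#' binding time (FRET-independent readout).
#'
#' @param concentration_nM protein concentration (>= 0).
#' @param kon_per_nM_per_s association rate constant (>= 0).
#' @param flow_time_s moment of flow in seconds.
#' @param pre_binding_model,post_binding_model [state_model()]s before/after
#'   binding.
#' @param pife_enhancement optional intensity enhancement factor (> 1) for
#'   PIFE assays; `NULL` for FRET assays.
#' @return An object of class `flow_assay_design`.
#' @export
flow_assay_design <- function(concentration_nM, kon_per_nM_per_s, flow_time_s,
                              pre_binding_model, post_binding_model,
                              pife_enhancement = NULL) {
  stopifnot(concentration_nM >= 0, kon_per_nM_per_s >= 0, flow_time_s >= 0,
            inherits(pre_binding_model, "state_model"),
            inherits(post_binding_model, "state_model"),
            is.null(pife_enhancement) || pife_enhancement > 1)
  structure(list(concentration_nM = concentration_nM,
                 kon_per_nM_per_s = kon_per_nM_per_s,
                 flow_time_s = flow_time_s,
                 pre_binding_model = pre_binding_model,
                 post_binding_model = post_binding_model,
                 pife_enhancement = pife_enhancement),
            class = "flow_assay_design")
}

#' Look up a named simulation preset
#'
#' Returns the fully parameterised default models for a named experimental
#' scenario. `flow_POT1(c)`-style presets are requested as
#' `preset("flow_POT1", concentration_nM = c)`.
#'
#' @param name preset name; see [preset_names()].
#' @param concentration_nM protein concentration for flow presets (nM).
#' @return A list with elements `model` ([state_model()]), `phys`
#'   ([photophysics()]), and optionally `flow` ([flow_assay_design()]) or
#'   `mixture` (named fractions over other presets).
#' @examples
#' preset("G4_free")$model$fret_means
#' @export
preset <- function(name, concentration_nM = 25) {
  reg <- preset_registry()
  if (identical(name, "flow_POT1")) {
    stopifnot(concentration_nM >= 0)
    return(list(
      model = state_model(0.30, matrix(0, 1, 1)),
      phys = photophysics(),
      flow = flow_assay_design(concentration_nM = concentration_nM,
                               kon_per_nM_per_s = 0.08,
                               flow_time_s = 10,
                               pre_binding_model = state_model(0.65, matrix(0, 1, 1)),
                               post_binding_model = state_model(0.30, matrix(0, 1, 1)))))
  }
  if (!name %in% names(reg))
    stop("unknown preset '", name, "'; valid presets: ",
         paste(c(names(reg), "flow_POT1"), collapse = ", "))
  reg[[name]]()
}

#' @rdname preset
#' @export
preset_names <- function() c(names(preset_registry()), "flow_POT1")

#' Simulate an ensemble of traces from one preset
#'
#' @param name preset name (equilibrium or flow).
#' @param n_traces number of traces.
#' @param seed integer seed; per-trace child seeds are derived from it.
#' @param n_frames frames per trace. Default 600 (60 s) for equilibrium
#'   presets; flow presets conventionally use 2000.
#' @param scheme an [excitation_scheme()].
#' @param phys optional [photophysics()] override.
#' @param concentration_nM forwarded to [preset()] for flow presets.
#' @return A [trace_set()]; each trace's `meta$label` records the preset.
#' @export
simulate_preset <- function(name, n_traces, seed, n_frames = 600,
                            scheme = excitation_scheme(), phys = NULL,
                            concentration_nM = 25) {
  p <- preset(name, concentration_nM = concentration_nM)
  if (!is.null(p$mixture))
    return(simulate_ensemble(p$mixture, n_traces, seed, n_frames = n_frames,
                             scheme = scheme, phys = phys,
                             ensemble_label = name))
  if (is.null(phys)) phys <- p$phys
  seeds <- derive_seeds(seed, n_traces)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    if (!is.null(p$flow)) {
      traces[[i]] <- simulate_flow_trace(p$flow, phys, scheme, n_frames,
                                         seed = seeds[i])
    } else {
      path <- simulate_state_path(p$model, n_frames * 0.1 + 1, seed = seeds[i])
      traces[[i]] <- render_trace(path, phys, scheme, n_frames,
                                  seed = seeds[i] + 1L)
    }
    traces[[i]]$meta$label <- name
  }
  trace_set(traces)
}

#' Simulate a labelled mixture ensemble
#'
#' Draws each trace's generating preset multinomially from `mixture` and
#' stores the ground-truth label in `meta$label` for recovery tests.
#'
#' @param mixture named numeric vector of fractions over preset names; must
#'   sum to 1 (tolerance 1e-9).
#' @inheritParams simulate_preset
#' @param ensemble_label optional label stored as `meta$ensemble`.
#' @return A [trace_set()].
#' @export
simulate_ensemble <- function(mixture, n_traces, seed, n_frames = 600,
                              scheme = excitation_scheme(), phys = NULL,
                              ensemble_label = NULL) {
  stopifnot(length(mixture) >= 1, !is.null(names(mixture)))
  if (abs(sum(mixture) - 1) > 1e-9)
    stop("mixture fractions must sum to 1 (got ", sum(mixture), ")")
  set.seed(as.integer(seed))
  labels <- sample(names(mixture), n_traces, replace = TRUE, prob = mixture)
  seeds <- derive_seeds(seed + 1L, n_traces)
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    p <- preset(labels[i])
    ph <- if (is.null(phys)) p$phys else phys
    path <- simulate_state_path(p$model, n_frames * 0.1 + 1, seed = seeds[i])
    tr <- render_trace(path, ph, scheme, n_frames, seed = seeds[i] + 1L)
    tr$meta$label <- labels[i]
    if (!is.null(ensemble_label)) tr$meta$ensemble <- ensemble_label
    traces[[i]] <- tr
  }
  trace_set(traces)
}

#' Simulate an equilibrium binding titration
#'
#' For each concentration, molecules are bound with probability
#' `c / (c + kd_nM)` (Langmuir equilibrium) and rendered from the bound or
#' unbound preset accordingly — the input for K_D estimation from ensemble
#' histograms. Default constructs: `"4R"` (unbound free G4 at 0.65, POT1
#' bound at 0.3, K_D 1.5 nM) and `"2R"` (unbound 0.8, monomer-POT1 bound
#' 0.6, K_D 1.4 nM).
#'
#' @param construct `"4R"` or `"2R"`.
#' @param concentrations_nM protein concentrations (nM).
#' @param n_traces molecules per concentration.
#' @param seed integer seed.
#' @param kd_nM ground-truth dissociation constant; default by construct.
#' @param n_frames frames per trace (default 40: short histogram movies).
#' @param scheme an [excitation_scheme()].
#' @return list with one [trace_set()] per concentration (names = nM), plus
#'   attributes `kd_nM`, `construct`, `bound_window` (the FRET window of the
#'   bound peak for [bound_fraction()]).
#' @export
simulate_titration <- function(construct = c("4R", "2R"), concentrations_nM,
                               n_traces, seed, kd_nM = NULL, n_frames = 40,
                               scheme = excitation_scheme()) {
  construct <- match.arg(construct)
  if (is.null(kd_nM)) kd_nM <- if (construct == "4R") 1.5 else 1.4
  presets <- if (construct == "4R") c(unbound = "G4_free", bound = "POT1_steady_4R")
             else c(unbound = "free_2R", bound = "POT1_steady_2R")
  bound_window <- if (construct == "4R") c(0.15, 0.45) else c(0.5, 0.7)
  set.seed(as.integer(seed))
  sub_seeds <- derive_seeds(seed, length(concentrations_nM))
  out <- lapply(seq_along(concentrations_nM), function(i) {
    cc <- concentrations_nM[i]
    f <- cc / (cc + kd_nM)
    simulate_ensemble(setNames(c(1 - f, f), presets)[c(1 - f, f) > 0],
                      n_traces, seed = sub_seeds[i], n_frames = n_frames,
                      scheme = scheme)
  })
  names(out) <- as.character(concentrations_nM)
  attr(out, "kd_nM") <- kd_nM
  attr(out, "construct") <- construct
  attr(out, "bound_window") <- bound_window
  out
}

#' Simulate a real-time flow-injection trace
#'
#' @param design a [flow_assay_design()].
#' @param phys a [photophysics()].
#' @param scheme an [excitation_scheme()].
#' @param n_frames frames per trace. Default 2000 (200 s).
#' @param seed integer seed.
#' @param frame_interval_s frame interval (s).
#' @return An [intensity_trace()] with `meta$flow_frame` (1-based frame of
#'   flow) and ground-truth `meta$true_binding_frame` (`NA` if the molecule
#'   never binds within the movie).
#' @export
simulate_flow_trace <- function(design, phys = photophysics(),
                                scheme = excitation_scheme(), n_frames = 2000,
                                seed, frame_interval_s = 0.1) {
  stopifnot(inherits(design, "flow_assay_design"),
            design$flow_time_s < n_frames * frame_interval_s)
  set.seed(as.integer(seed))
  rate <- design$kon_per_nM_per_s * design$concentration_nM
  t_bind <- if (rate > 0) design$flow_time_s + rexp(1, rate) else Inf
  dur <- n_frames * frame_interval_s + 1

  pre <- simulate_state_path(design$pre_binding_model, dur, seed = seed + 1L)
  if (is.finite(t_bind) && t_bind < dur) {
    post <- simulate_state_path(design$post_binding_model, dur - t_bind,
                                seed = seed + 2L)
    pre_keep <- pre[pre$entry_time_s < t_bind, , drop = FALSE]
    post$entry_time_s <- post$entry_time_s + t_bind
    kpre <- length(attr(pre, "model")$fret_means)
    post$state <- post$state + kpre
    combined <- rbind(pre_keep, post)
    model <- state_model(
      c(attr(pre, "model")$fret_means, attr(post, "model")$fret_means),
      matrix(0, kpre + length(attr(post, "model")$fret_means),
             kpre + length(attr(post, "model")$fret_means)),
      initial_distribution = c(attr(pre, "model")$initial_distribution,
                               rep(0, length(attr(post, "model")$fret_means))))
    path <- structure(combined, duration_s = dur, model = model,
                      class = c("state_path", "data.frame"))
  } else {
    path <- pre
  }

  tr <- render_trace(path, phys, scheme, n_frames, seed = seed + 3L,
                     frame_interval_s = frame_interval_s)
  if (!is.null(design$pife_enhancement) && is.finite(t_bind) &&
      t_bind < n_frames * frame_interval_s) {
    bf <- 1L + floor(t_bind / frame_interval_s)
    idx <- bf:n_frames
    bg <- phys$background
    tr$donor[idx] <- (tr$donor[idx] - bg) * design$pife_enhancement + bg
    tr$acceptor[idx] <- (tr$acceptor[idx] - bg) * design$pife_enhancement + bg
  }
  tr$meta$flow_frame <- 1L + floor(design$flow_time_s / frame_interval_s)
  tr$meta$true_binding_frame <-
    if (is.finite(t_bind) && t_bind < n_frames * frame_interval_s)
      1L + floor(t_bind / frame_interval_s) else NA_integer_
  tr$meta$concentration_nM <- design$concentration_nM
  tr
}
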