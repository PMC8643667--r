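#' Build or load a pipeline run configuration
#'
#' A declarative description of one analysis run: either an input trace file
#' or a simulation preset, the analysis thresholds, a mandatory seed, and an
#' output directory. Thresholds are validated against their documented
#' ranges. Configurations round-trip through YAML without loss.
#'
#' @param input path to a trace file (TSV or legacy binary), or `NULL` to
#'   simulate.
#' @param preset simulation preset name (see [preset_names()]) when
#'   simulating.
#' @param n_traces,n_frames simulation size.
#' @param seed integer seed (mandatory; drives every stochastic stage).
#' @param out_dir output directory.
#' @param leakage leakage used by [compute_fret()] (`NULL`: the simulated
#'   traces' own metadata value, else 0).
#' @param amplitude_threshold,high_threshold [classify_trace()] thresholds.
#' @param merge_tol,min_occupancy,k_range [select_states()] settings.
#' @param min_dwell_frames [extract_transitions()] floor.
#' @param hist_bin_width,tdp_bin_width histogram/TDP bin widths.
#' @param run_hmm fit HMMs and build the TDP? (The slowest stage; default
#'   TRUE.)
#' @return An object of class `run_config` (a validated named list).
#' @export
run_config <- function(input = NULL, preset = "POT1_only", n_traces = 50,
                       n_frames = 600, seed = 1, out_dir = tempfile("telodyn_"),
                       leakage = NULL, amplitude_threshold = 0.15,
                       high_threshold = 0.6, merge_tol = 0.07,
                       min_occupancy = 0.02, k_range = 2:8,
                       min_dwell_frames = 2, hist_bin_width = 0.02,
                       tdp_bin_width = 0.03, run_hmm = TRUE) {
  stopifnot(is.null(input) || file.exists(input),
            amplitude_threshold > 0, amplitude_threshold < 0.5,
            high_threshold > 0, high_threshold < 1,
            merge_tol > 0, merge_tol < 0.3,
            min_occupancy >= 0, min_occupancy < 0.5,
            min_dwell_frames >= 1,
            hist_bin_width > 0, tdp_bin_width > 0)
  if (is.null(seed)) stop("a seed is mandatory for every stochastic stage")
  if (is.null(input)) {
    stopifnot(preset %in% preset_names())
    if (n_traces < 1) stop("n_traces must be >= 1")
  }
  structure(list(input = input, preset = preset, n_traces = n_traces,
                 n_frames = n_frames, seed = as.integer(seed),
                 out_dir = out_dir, leakage = leakage,
                 amplitude_threshold = amplitude_threshold,
                 high_threshold = high_threshold, merge_tol = merge_tol,
                 min_occupancy = min_occupancy, k_range = k_range,
                 min_dwell_frames = min_dwell_frames,
                 hist_bin_width = hist_bin_width,
                 tdp_bin_width = tdp_bin_width, run_hmm = run_hmm),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$k_range)) cfg$k_range <- as.integer(cfg$k_range)
  do.call(run_config, cfg)
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$k_range <- as.integer(cfg$k_range)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> trace processing -> classification ->
#' histogram -> HMM/TDP -> dwell kinetics, writing one structured results
#' file per stage under `config$out_dir` plus a run manifest with input and
#' output hashes. Re-running the same configuration and seed reproduces
#' byte-identical structured outputs.
#'
#' Stage outputs: `traces.tsv` (simulated input, when simulating),
#' `fret.tsv` (per-frame corrected efficiencies), `classes.tsv` (per-trace
#' label, baseline, fraction of time dynamic — the violin-plot table),
#' `fractions.json`, `histogram.tsv`, `tdp.tsv` (transition records),
#' `levels.json`, `dwells.tsv`, `dwell_fit.json`, `manifest.json`.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages?
#' @return The run manifest (list), invisibly the same as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  stage_times <- list()
  tick <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stage_times[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    say("stage ", name, " done (", stage_times[[name]], " s)")
    res
  }
  outputs <- character(0)
  emit <- function(fname) outputs <<- c(outputs, file.path(config$out_dir, fname))

  traces <- tick("input", {
    if (is.null(config$input)) {
      ts <- simulate_preset(config$preset, config$n_traces, config$seed,
                            n_frames = config$n_frames)
      write_traces(ts, file.path(config$out_dir, "traces.tsv"))
      emit("traces.tsv")
      ts
    } else read_traces(config$input)
  })

  fret <- tick("process", {
    fr <- process_traces(traces, leakage = config$leakage)
    df <- do.call(rbind, lapply(seq_along(fr), function(i)
      data.frame(trace_id = i, frame = fr[[i]]$frame_index,
                 time_s = fr[[i]]$time_s,
                 efficiency = round(fr[[i]]$efficiency, 6),
                 valid = fr[[i]]$valid_mask)))
    write.table(df, file.path(config$out_dir, "fret.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("fret.tsv")
    fr
  })

  classes <- tick("classify", {
    cl <- classify_traces(fret,
                          amplitude_threshold = config$amplitude_threshold,
                          high_threshold = config$high_threshold)
    df <- data.frame(trace_id = seq_along(cl),
                     label = vapply(cl, function(x) x$label, ""),
                     baseline = vapply(cl, function(x) x$baseline, 0),
                     n_excursions = vapply(cl, function(x)
                       as.integer(x$n_excursions), 0L),
                     fraction_dynamic_time = vapply(cl, function(x)
                       x$fraction_dynamic_time, 0))
    write.table(df, file.path(config$out_dir, "classes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("classes.tsv")
    fr <- summarize_fractions(cl, seed = config$seed)
    jsonlite::write_json(list(fractions = as.list(fr$fractions),
                              dynamic_total = fr$dynamic_total, n = fr$n),
                         file.path(config$out_dir, "fractions.json"),
                         auto_unbox = TRUE, digits = NA)
    emit("fractions.json")
    cl
  })

  tick("histogram", {
    h <- build_histogram(fret, bin_width = config$hist_bin_width)
    write.table(data.frame(mid = h$mids, density = h$density,
                           counts = h$counts),
                file.path(config$out_dir, "histogram.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("histogram.tsv")
    h
  })

  if (config$run_hmm) {
    tick("hmm_tdp", {
      dyn <- which(vapply(classes, function(x)
        x$label %in% c("dynamicI", "dynamicII", "dynamicI_II"), TRUE))
      if (length(dyn) >= 1L) {
        fits <- lapply(dyn, function(i)
          select_states(fret[[i]], k_range = config$k_range,
                        seed = config$seed + i, merge_tol = config$merge_tol,
                        min_occupancy = config$min_occupancy))
        trans <- pool_transitions(fits,
                                  min_dwell_frames = config$min_dwell_frames)
        write.table(as.data.frame(trans), file.path(config$out_dir, "tdp.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        emit("tdp.tsv")
        lv <- if (nrow(trans) >= 20)
          count_tdp_levels(trans, bandwidth = config$merge_tol)
        else list(n_levels = NA_integer_, centers = numeric(0))
        jsonlite::write_json(lv, file.path(config$out_dir, "levels.json"),
                             auto_unbox = TRUE, digits = NA)
        emit("levels.json")
      }
    })
  }

  tick("kinetics", {
    dw <- extract_dwells(fret, classes = classes)
    write.table(data.frame(dwell_s = dw),
                file.path(config$out_dir, "dwells.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    emit("dwells.tsv")
    if (length(dw) >= 10) {
      f <- fit_exponential(dw, seed = config$seed)
      jsonlite::write_json(list(tau_s = f$tau_s, ci95 = f$ci95,
                                n_events = f$n_events, method = f$method),
                           file.path(config$out_dir, "dwell_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("dwell_fit.json")
    }
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("telodyn")),
    config = unclass(config),
    stage_seconds = stage_times,
    input_hash = if (!is.null(config$input))
      unname(tools::md5sum(config$input)) else NA,
    output_hashes = as.list(tools::md5sum(outputs)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
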