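#' Classify a FRET trace as steady, Dynamic-I, or Dynamic-II
#'
#' Implements the trace taxonomy used for POT1-bound overhang dynamics:
#' excursions are departures of the 3-frame median-filtered efficiency from
#' the per-trace baseline (the mode of its FRET histogram, robust to
#' excursions) by more than the amplitude threshold `A`. Candidate excursions
#' are confirmed with a dual-threshold (hysteresis) rule — at least one
#' filtered frame must deviate by `peak_factor * A` — so that camera noise
#' runs just above `A` are not called dynamic, while excursion entry/exit
#' (and hence dwell timing) stays at the single `A` crossing.
#'
#' A trace with no excursion is `steady`; a trace whose excursion plateaus
#' all stay below the high-FRET threshold `H` is `dynamicI` (slow
#' oscillations confined below ~0.6); a trace with only high excursions is
#' `dynamicII` (sharp spikes reaching above ~0.6, up to ~0.9); traces
#' showing both kinds are `dynamicI_II`. An excursion counts as high when
#' its plateau estimate (the median of the filtered segment) clears `H` by
#' `high_margin_se` standard errors of that median, so that a plateau merely
#' straddling `H` through noise is not promoted. Excursions may run above or
#' below the baseline (downward excursions, as in the monomer 2R construct,
#' count by amplitude; their plateau sits below baseline and is never high).
#'
#' @param trace a `fret_trace` from [compute_fret()] with >= `min_frames`
#'   valid frames; shorter traces return the `unclassified` sentinel.
#' @param amplitude_threshold excursion amplitude `A` (default 0.15).
#' @param high_threshold Dynamic-II plateau threshold `H` (default 0.6).
#' @param median_k median prefilter width in frames (odd, default 3).
#' @param min_excursion_frames minimum excursion length in filtered frames
#'   (default 2, the camera-limited detection floor).
#' @param peak_factor hysteresis confirmation multiple of `A` (default 1.5).
#' @param high_margin_se noise margin, in standard errors of the segment
#'   median, required above `H` for a high call (default 2; 0 recovers the
#'   raw comparison).
#' @param min_frames minimum valid frames to classify (default 50).
#' @return An object of class `trace_class`: list with `label` in
#'   `{steady, dynamicI, dynamicII, dynamicI_II, unclassified}`,
#'   `fraction_dynamic_time`, `n_excursions`, `baseline`, `noise_sd`, and
#'   `excursions` (data.frame `start`, `end`, `apex` (plateau estimate),
#'   `peak`, `dwell_s`, `censored` — start/end index the valid green frames).
#' @export
classify_trace <- function(trace, amplitude_threshold = 0.15,
                           high_threshold = 0.6, median_k = 3,
                           min_excursion_frames = 2, peak_factor = 1.5,
                           high_margin_se = 2, min_frames = 50) {
  stopifnot(inherits(trace, "fret_trace"))
  e <- valid_efficiency(trace)
  empty <- data.frame(start = integer(0), end = integer(0),
                      apex = numeric(0), peak = numeric(0),
                      dwell_s = numeric(0), censored = logical(0))
  if (length(e) < min_frames) {
    return(structure(list(label = "unclassified", fraction_dynamic_time = NA_real_,
                          n_excursions = NA_integer_, baseline = NA_real_,
                          noise_sd = NA_real_, excursions = empty),
                     class = "trace_class"))
  }
  ef <- if (median_k > 1) as.numeric(runmed(e, median_k)) else e
  baseline <- fret_mode(ef)
  dev <- ef - baseline
  out <- abs(dev) > amplitude_threshold
  # robust noise scale of the filtered trace around its baseline
  quiet <- ef[!out]
  nsd <- if (length(quiet) > 5) stats::mad(quiet, center = baseline) else 0

  # baseline returns shorter than the detection floor cannot be resolved by
  # the camera any more than excursions that short; absorb them so the floor
  # acts symmetrically and noise flickers do not split one excursion in two
  r <- rle(out)
  if (length(r$lengths) > 2L) {
    interior <- 2:(length(r$lengths) - 1L)
    fill <- interior[!r$values[interior] &
                       r$lengths[interior] < min_excursion_frames]
    if (length(fill)) {
      r$values[fill] <- TRUE
      out <- inverse.rle(r)
      r <- rle(out)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_excursion_frames
  exc <- empty
  # dwells are measured in wall-clock time between entry and exit frames so
  # that excursions bridging dark/red excitation blocks keep their duration
  gidx <- trace$frame_index[trace$valid_mask]
  if (any(keep)) {
    s <- starts[keep]; en <- ends[keep]
    apex <- numeric(length(s)); peak <- numeric(length(s))
    for (i in seq_along(s)) {
      seg <- ef[s[i]:en[i]]
      apex[i] <- median(seg)
      peak[i] <- seg[which.max(abs(seg - baseline))]
    }
    confirmed <- abs(peak - baseline) >= peak_factor * amplitude_threshold
    exc <- data.frame(start = s, end = en, apex = apex, peak = peak,
                      dwell_s = (gidx[en] - gidx[s] + 1L) *
                        trace$frame_interval_s,
                      censored = s == 1L | en == length(ef))[confirmed, ,
                                                            drop = FALSE]
    rownames(exc) <- NULL
  }

  n_exc <- nrow(exc)
  frac <- if (n_exc) sum(exc$end - exc$start + 1L) / length(ef) else 0
  if (n_exc == 0L) {
    label <- "steady"
  } else {
    len <- exc$end - exc$start + 1L
    margin <- high_margin_se * 1.2533 * nsd / sqrt(len)   # SE of a median
    hi <- exc$apex >= high_threshold + margin
    label <- if (all(hi)) "dynamicII" else if (any(hi)) "dynamicI_II" else "dynamicI"
  }
  structure(list(label = label, fraction_dynamic_time = frac,
                 n_excursions = n_exc, baseline = baseline, noise_sd = nsd,
                 excursions = exc),
            class = "trace_class")
}

#' @export
print.trace_class <- function(x, ...) {
  cat("trace_class:", x$label)
  if (!is.na(x$fraction_dynamic_time))
    cat(sprintf(" (baseline %.2f, %d excursion(s), %.0f%% dynamic time)",
                x$baseline, x$n_excursions, 100 * x$fraction_dynamic_time))
  cat("\n")
  invisible(x)
}

# Mode of a FRET sample via its histogram (0.02 bins), refined as the mean
# of values within +/- 0.05 of the mode bin; robust baseline even when
# excursions occupy a large time fraction.
fret_mode <- function(e, bin = 0.02, refine = 0.05) {
  edges <- seq(-0.2, 1.2 + bin / 2, by = bin)
  cnt <- tabulate(findInterval(pmin(pmax(e, -0.2), 1.2 - 1e-12), edges),
                  nbins = length(edges) - 1L)
  m <- edges[which.max(cnt)] + bin / 2
  near <- abs(e - m) <= refine
  if (any(near)) mean(e[near]) else m
}

#' Classify every trace in a set
#'
#' @param traces `fret_trace` objects (see [compute_fret()]).
#' @param ... passed to [classify_trace()].
#' @return list of `trace_class` objects.
#' @export
classify_traces <- function(traces, ...) {
  lapply(traces, classify_trace, ...)
}

#' Summarize population fractions of trace classes
#'
#' Fractions of steady/Dynamic-I/Dynamic-II(/mixed) traces with nonparametric
#' bootstrap confidence intervals. For the conventional three-way summary,
#' mixed `dynamicI_II` traces are counted within `dynamicII`
#' (`three_way = TRUE`, default); the four-way breakdown is retained in
#' `counts`.
#'
#' @param classes list of `trace_class` objects; `unclassified` traces are
#'   excluded.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param three_way fold `dynamicI_II` into `dynamicII`?
#' @return An object of class `class_fractions`: list with `fractions`,
#'   `counts` (four-way), `n`, `ci_lower`, `ci_upper`,
#'   `dynamic_total` (fraction dynamic of any kind) and its CI.
#' @export
summarize_fractions <- function(classes, n_boot = 1000, seed = 1,
                                three_way = TRUE) {
  labs <- vapply(classes, function(cl) cl$label, "")
  labs <- labs[labs != "unclassified"]
  if (length(labs) == 0L) stop("no classified traces")
  lv4 <- c("steady", "dynamicI", "dynamicII", "dynamicI_II")
  counts4 <- table(factor(labs, levels = lv4))
  labs_eff <- if (three_way) ifelse(labs == "dynamicI_II", "dynamicII", labs) else labs
  lv <- if (three_way) c("steady", "dynamicI", "dynamicII") else lv4
  n <- length(labs_eff)
  frac <- as.numeric(table(factor(labs_eff, levels = lv))) / n
  names(frac) <- lv
  dyn <- mean(labs_eff != "steady")

  set.seed(as.integer(seed))
  boot <- matrix(0, n_boot, length(lv) + 1L)
  for (b in seq_len(n_boot)) {
    rs <- labs_eff[sample.int(n, n, replace = TRUE)]
    boot[b, ] <- c(as.numeric(table(factor(rs, levels = lv))) / n,
                   mean(rs != "steady"))
  }
  ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975))
  structure(list(fractions = frac, counts = as.numeric(counts4),
                 n = n,
                 ci_lower = setNames(ci[1, seq_along(lv)], lv),
                 ci_upper = setNames(ci[2, seq_along(lv)], lv),
                 dynamic_total = dyn,
                 dynamic_ci = ci[, length(lv) + 1L]),
            class = "class_fractions")
}

#' @export
print.class_fractions <- function(x, ...) {
  cat("class_fractions (n =", x$n, "):\n")
  tab <- data.frame(fraction = x$fractions, ci_lo = x$ci_lower,
                    ci_hi = x$ci_upper)
  print(round(tab, 3))
  cat(sprintf("dynamic total: %.3f [%.3f, %.3f]\n", x$dynamic_total,
              x$dynamic_ci[1], x$dynamic_ci[2]))
  invisible(x)
}

#' Compare two arms of replicate fractions (two-sample t test)
#'
#' Classical equal-variance two-tailed two-sample Student's t test on
#' per-replicate fractions, as used to compare condition-level population
#' fractions. A zero pooled variance is guarded by a small epsilon so that
#' identical arms give `t = 0, p = 1` and fully separated degenerate arms
#' give `p ~ 0`.
#'
#' @param a,b numeric vectors of per-replicate fractions (>= 2 each).
#' @param eps variance guard. Default 1e-12.
#' @return list with `t`, `df`, `p`.
#' @export
compare_fractions <- function(a, b, eps = 1e-12) {
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 replicates per arm are required")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  se <- sqrt(max(sp2, 0)) * sqrt(1 / na + 1 / nb)
  tstat <- (mean(a) - mean(b)) / max(se, eps)
  df <- na + nb - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}
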