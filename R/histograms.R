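#' Build a normalized ensemble FRET histogram
#'
#' Pools the first `frames_per_molecule` valid green frames of each trace
#' (mirroring short-movie ensemble histograms built from thousands of
#' molecules) into a density-normalized histogram over `[-0.1, 1.1]`.
#'
#' @param traces a [trace_set()] of `fret_trace` objects (see
#'   [compute_fret()]), or a list of them. Donor-only traces are assumed
#'   excluded upstream.
#' @param frames_per_molecule frames used per molecule (default 10, the green
#'   ALEX block length; only green frames carry FRET). `Inf` pools all valid
#'   frames.
#' @param bin_width histogram bin width (default 0.02; the coarse 0.2 used
#'   for dynamic-range heatmap histograms is available via this argument).
#' @param limits histogram support. Default `c(-0.1, 1.1)`.
#' @return An object of class `fret_histogram`: list with `bin_edges`,
#'   `mids`, `density` (integrates to 1), `counts`, `n_molecules`,
#'   `frames_per_molecule`, `bin_width`.
#' @export
build_histogram <- function(traces, frames_per_molecule = 10,
                            bin_width = 0.02, limits = c(-0.1, 1.1)) {
  if (length(traces) == 0L) stop("empty trace set")
  vals <- unlist(lapply(traces, function(ft) {
    stopifnot(inherits(ft, "fret_trace"))
    e <- valid_efficiency(ft)
    head(e, frames_per_molecule)
  }))
  if (length(vals) == 0L) stop("no valid frames to histogram")
  edges <- seq(limits[1], limits[2] + bin_width / 2, by = bin_width)
  vals <- pmin(pmax(vals, limits[1]), limits[2] - 1e-12)
  counts <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  dens <- counts / (sum(counts) * bin_width)
  structure(list(bin_edges = edges, mids = edges[-length(edges)] + bin_width / 2,
                 density = dens, counts = counts,
                 n_molecules = length(traces),
                 frames_per_molecule = frames_per_molecule,
                 bin_width = bin_width),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("fret_histogram:", x$n_molecules, "molecules, bin width", x$bin_width,
      "\n  mode at E =", x$mids[which.max(x$density)], "\n")
  invisible(x)
}

#' @export
plot.fret_histogram <- function(x, ...) {
  graphics::plot(x$mids, x$density, type = "s", xlab = "FRET efficiency",
                 ylab = "density", ...)
  invisible(x)
}

#' Fit a sum of Gaussians to a FRET histogram
#'
#' Least-squares fit of `sum_i w_i * dnorm(E, mu_i, s_i)` to the binned
#' density with unrestrained peak centers, the way ensemble smFRET histograms
#' are conventionally fitted. Initialization from local density peaks;
#' components are returned sorted by mean.
#'
#' @param hist a `fret_histogram`.
#' @param n_components number of Gaussian components (>= 1).
#' @param sd_init initial component SD (default 0.07).
#' @param init_means optional starting peak centers (length `n_components`),
#'   e.g. the known FRET levels of a construct; defaults to local density
#'   peaks. Centers remain unrestrained in the fit.
#' @param equal_sd constrain all components to one common width? Useful for
#'   strongly overlapping peaks of the same construct, whose widths are set
#'   by the same shot noise; an unconstrained broad component otherwise
#'   swallows weight from its neighbour. Default FALSE.
#' @return An object of class `gaussian_fit`: list with `components`
#'   (data.frame `weight`, `mean`, `sd`), `rss`, `fitted`, `hist`.
#' @export
fit_gaussians <- function(hist, n_components, sd_init = 0.07,
                          init_means = NULL, equal_sd = FALSE) {
  stopifnot(inherits(hist, "fret_histogram"), n_components >= 1)
  x <- hist$mids; y <- hist$density
  k <- n_components
  if (is.null(init_means)) {
    init_means <- find_peaks(x, y, k)$m
  } else stopifnot(length(init_means) == k)
  ks <- if (equal_sd) 1L else k
  par0 <- c(w = rep(1 / k, k), m = init_means, s = rep(sd_init, ks))

  model_fun <- function(p) {
    w <- p[1:k]; m <- p[(k + 1):(2 * k)]
    s <- rep_len(p[(2 * k + 1):(2 * k + ks)], k)
    rowSums(vapply(seq_len(k),
                   function(i) w[i] * dnorm(x, m[i], abs(s[i]) + 1e-6),
                   numeric(length(x))))
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0,
                       fn = function(p) y - model_fun(p),
                       lower = c(rep(0, k), rep(-0.2, k), rep(0.01, ks)),
                       upper = c(rep(1.2, k), rep(1.2, k), rep(0.5, ks)),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Gaussian fit failed to converge: ",
                             conditionMessage(e)))
  p <- fit$par
  comp <- data.frame(weight = p[1:k], mean = p[(k + 1):(2 * k)],
                     sd = abs(rep_len(p[(2 * k + 1):(2 * k + ks)], k)))
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp,
                 rss = sum((y - model_fun(fit$par))^2),
                 fitted = model_fun(fit$par), hist = hist),
            class = "gaussian_fit")
}

# Crude peak finder on binned density: local maxima ranked by height, padded
# with quantile-spread positions when fewer peaks than components exist.
find_peaks <- function(x, y, k) {
  n <- length(y)
  is_pk <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n], FALSE) &
    y > max(y) * 0.05
  ord <- order(y, decreasing = TRUE)
  pk <- ord[is_pk[ord]]
  m <- x[head(pk, k)]
  if (length(m) < k)
    m <- c(m, seq(0.2, 0.8, length.out = k - length(m) + 2)[-c(1, k - length(m) + 2)])
  list(m = m, w = rep(1 / k, k))
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat("gaussian_fit with", nrow(x$components), "component(s), rss =",
      signif(x$rss, 4), "\n")
  print(x$components, digits = 4)
  invisible(x)
}

#' @export
plot.gaussian_fit <- function(x, ...) {
  plot(x$hist, ...)
  graphics::lines(x$hist$mids, x$fitted, col = "red", lwd = 2)
  invisible(x)
}

#' Bound fraction from a Gaussian mixture fit
#'
#' The fraction of molecules in the protein-bound population: the summed
#' weight of fitted components whose means lie inside `bound_window`, divided
#' by the total weight.
#'
#' @param fit a `gaussian_fit`.
#' @param bound_window FRET interval of the bound peak. Default
#'   `c(0.15, 0.45)` (the POT1-bound ~0.3 peak of the 4R construct).
#' @return fraction in `[0, 1]`.
#' @export
bound_fraction <- function(fit, bound_window = c(0.15, 0.45)) {
  stopifnot(inherits(fit, "gaussian_fit"), nrow(fit$components) >= 1)
  m <- fit$components$mean; w <- fit$components$weight
  tot <- sum(w)
  if (tot <= 0) return(0)
  sum(w[m >= bound_window[1] & m <= bound_window[2]]) / tot
}

#' Build a time-resolved FRET heatmap
#'
#' 2D occupancy of (time, FRET) across traces, each time column normalized to
#' unit sum. With `sync = "event"` each trace is aligned at its event frame
#' (e.g. the detected protein-binding moment), producing post-synchronized
#' heatmaps; with `sync = "none"` traces align at frame 0.
#'
#' @param traces `fret_trace` objects.
#' @param sync `"none"` or `"event"`.
#' @param event_frames with `sync = "event"`, one green-frame event index per
#'   trace (index into the trace's green frames); traces with `NA` events are
#'   skipped with a warning count.
#' @param fret_bin FRET bin width (default 0.02).
#' @param time_window with `sync = "event"`, seconds kept around the event.
#' @return An object of class `fret_heatmap`: list with `time_s`, `fret_mids`,
#'   `density` (FRET x time, columns normalized or flagged empty),
#'   `n_traces`, `n_skipped`, `sync`.
#' @export
build_heatmap <- function(traces, sync = c("none", "event"),
                          event_frames = NULL, fret_bin = 0.02,
                          time_window = c(-10, 30)) {
  sync <- match.arg(sync)
  stopifnot(length(traces) >= 1)
  dt <- traces[[1]]$frame_interval_s
  edges <- seq(0, 1 + fret_bin / 2, by = fret_bin)
  nbin <- length(edges) - 1L
  n_skipped <- 0L

  if (sync == "none") {
    n_t <- max(vapply(traces, function(ft) length(ft$efficiency), 0L))
    offsets <- rep(0L, length(traces))
    t_axis <- (seq_len(n_t) - 1) * dt
  } else {
    if (is.null(event_frames) || length(event_frames) != length(traces))
      stop("sync = 'event' requires one event frame per trace")
    lo <- floor(time_window[1] / dt); hi <- ceiling(time_window[2] / dt)
    n_t <- hi - lo + 1L
    t_axis <- (lo:hi) * dt
  }

  M <- matrix(0, nbin, n_t)
  for (i in seq_along(traces)) {
    ft <- traces[[i]]
    e <- ifelse(ft$valid_mask, ft$efficiency, NA_real_)
    if (sync == "event") {
      ev <- event_frames[i]
      if (is.na(ev)) { n_skipped <- n_skipped + 1L; next }
      cols <- seq_along(e) - ev - lo + 1L
    } else {
      cols <- seq_along(e)
    }
    keep <- !is.na(e) & cols >= 1L & cols <= n_t
    if (!any(keep)) next
    b <- findInterval(pmin(pmax(e[keep], 0), 1 - 1e-12), edges,
                      rightmost.closed = TRUE)
    for (j in seq_along(b)) M[b[j], cols[keep][j]] <- M[b[j], cols[keep][j]] + 1
  }
  if (n_skipped > 0L)
    warning(n_skipped, " trace(s) without an event frame were skipped")
  colsum <- colSums(M)
  dens <- sweep(M, 2, pmax(colsum, 1), "/")
  structure(list(time_s = t_axis, fret_mids = edges[-length(edges)] + fret_bin / 2,
                 density = dens, empty_columns = colsum == 0,
                 n_traces = length(traces) - n_skipped, n_skipped = n_skipped,
                 sync = sync),
            class = "fret_heatmap")
}

#' @export
print.fret_heatmap <- function(x, ...) {
  cat("fret_heatmap (", x$sync, "-synchronized): ", x$n_traces, " traces, ",
      length(x$time_s), " time bins\n", sep = "")
  invisible(x)
}

#' @export
plot.fret_heatmap <- function(x, ...) {
  graphics::image(x$time_s, x$fret_mids, t(x$density),
                  xlab = "time (s)", ylab = "FRET efficiency",
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' Dynamic-range heatmap histogram
#'
#' Pools every valid frame of pre-classified dynamic traces into a single
#' occupancy histogram and reports the span of occupied FRET values — the
#' "FRET heatmap histogram" used to compare the dynamic range across
#' constructs and protein conditions. Trajectories are 3-frame
#' median-filtered first (as when such heatmaps are displayed), and the span
#' is read at a visual-occupancy cut: bins below `occupancy_min` of the peak
#' density are treated as empty, so sparse noise tails do not extend the
#' reported range.
#'
#' @param dynamic_traces `fret_trace` objects pre-classified as dynamic.
#' @param bin_size bin width (default 0.02; 0.2 reproduces coarse published
#'   binning).
#' @param occupancy_min minimum bin density (relative to the maximum) counted
#'   as occupied when reporting the span. Default 0.1.
#' @param median_k median prefilter width in frames (odd; 1 disables).
#' @return A `fret_histogram` with extra fields `span` (`c(min, max)` of
#'   occupied FRET) and `occupied_bins`.
#' @export
fret_range_heatmap <- function(dynamic_traces, bin_size = 0.02,
                               occupancy_min = 0.1, median_k = 3) {
  vals <- unlist(lapply(dynamic_traces, function(ft) {
    e <- valid_efficiency(ft)
    if (median_k > 1 && length(e) > median_k) as.numeric(runmed(e, median_k))
    else e
  }))
  if (length(vals) == 0L) stop("no valid frames to histogram")
  edges <- seq(0, 1 + bin_size / 2, by = bin_size)
  vals <- pmin(pmax(vals, 0), 1 - 1e-12)
  counts <- tabulate(findInterval(vals, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1L)
  dens <- counts / (sum(counts) * bin_size)
  h <- structure(list(bin_edges = edges,
                      mids = edges[-length(edges)] + bin_size / 2,
                      density = dens, counts = counts,
                      n_molecules = length(dynamic_traces),
                      frames_per_molecule = Inf, bin_width = bin_size),
                 class = "fret_histogram")
  occ <- h$density >= occupancy_min * max(h$density)
  h$occupied_bins <- occ
  h$span <- if (any(occ)) {
    c(h$bin_edges[min(which(occ))], h$bin_edges[max(which(occ)) + 1L])
  } else c(NA_real_, NA_real_)
  h
}
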