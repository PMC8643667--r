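#' Read and write trace sets
#'
#' Two on-disk dialects are supported:
#' \describe{
#'   \item{TSV (`.tsv`, `.txt`)}{flat table with columns `trace_id`, `frame`,
#'     `excitation`, `donor`, `acceptor`; the frame interval and per-trace
#'     metadata ride in `#!`-prefixed header lines, making the round trip
#'     lossless. A file without an `excitation` column is accepted and
#'     defaults to all-green with a warning.}
#'   \item{legacy binary (`.traces`)}{the interleaved 16-bit dialect used by
#'     classic smFRET acquisition code: a 32-bit integer frame count, a
#'     16-bit trace count (donor/acceptor channels counted separately), then
#'     frame-major interleaved channel shorts. Metadata is not representable
#'     and is lost (documented).}
#' }
#' HDF5 layouts are not supported by this build and raise an error naming the
#' supported dialects.
#'
#' @param path file path; the dialect follows the extension.
#' @param frame_interval_s frame interval for dialects that do not store it.
#' @return `read_traces()` returns a [trace_set()]; `write_traces()` returns
#'   `path` invisibly.
#' @export
read_traces <- function(path, frame_interval_s = 0.1) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = , txt = read_traces_tsv(path),
         traces = read_traces_legacy(path, frame_interval_s),
         h5 = , hdf5 = stop("HDF5 trace files are not supported; ",
                            "use the TSV or legacy .traces dialect"),
         stop("unrecognised trace file extension '.", ext, "'"))
}

#' @rdname read_traces
#' @param traces a [trace_set()] (or list of [intensity_trace()]).
#' @export
write_traces <- function(traces, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = , txt = write_traces_tsv(traces, path),
         traces = write_traces_legacy(traces, path),
         h5 = , hdf5 = stop("HDF5 trace files are not supported; ",
                            "use the TSV or legacy .traces dialect"),
         stop("unrecognised trace file extension '.", ext, "'"))
  invisible(path)
}

# -- TSV dialect --------------------------------------------------------------

serialize_meta <- function(meta) {
  keep <- vapply(meta, function(v) is.atomic(v) && length(v) >= 1, TRUE)
  m <- meta[keep]
  if (!length(m)) return(character(0))
  vapply(names(m), function(k)
    paste0(k, "=", paste(format(m[[k]], digits = 15, trim = TRUE,
                                scientific = FALSE), collapse = ",")),
    "")
}

deserialize_meta <- function(fields) {
  out <- list()
  for (f in fields) {
    kv <- strsplit(f, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    vals <- strsplit(kv[2], ",", fixed = TRUE)[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[1]]] <- if (!anyNA(num)) num else vals
  }
  out
}

write_traces_tsv <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dt <- if (length(traces)) traces[[1]]$frame_interval_s else 0.1
  writeLines(sprintf("#! frame_interval_s\t%.10g", dt), con)
  for (i in seq_along(traces)) {
    ms <- serialize_meta(traces[[i]]$meta)
    if (length(ms))
      writeLines(sprintf("#! meta\t%d\t%s", i, paste(ms, collapse = "\t")), con)
  }
  writeLines("trace_id\tframe\texcitation\tdonor\tacceptor", con)
  for (i in seq_along(traces)) {
    tr <- traces[[i]]
    df <- data.frame(trace_id = i, frame = seq_along(tr$donor),
                     excitation = tr$excitation,
                     donor = format(tr$donor, digits = 15, trim = TRUE,
                                    scientific = FALSE),
                     acceptor = format(tr$acceptor, digits = 15, trim = TRUE,
                                       scientific = FALSE))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

read_traces_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#!", lines)
  dt <- 0.1
  metas <- list()
  for (h in lines[hdr]) {
    parts <- strsplit(sub("^#!\\s*", "", h), "\t", fixed = TRUE)[[1]]
    if (parts[1] == "frame_interval_s") dt <- as.numeric(parts[2])
    if (parts[1] == "meta")
      metas[[as.integer(parts[2])]] <- deserialize_meta(parts[-(1:2)])
  }
  body <- lines[!hdr]
  if (!length(body)) stop("malformed TSV: no data rows in ", path)
  df <- tryCatch(
    read.table(text = body, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE),
    error = function(e) stop("malformed TSV (", conditionMessage(e),
                             ") in ", path))
  need <- c("trace_id", "frame", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("malformed TSV: missing column(s) ",
         paste(setdiff(need, names(df)), collapse = ", "), " in ", path)
  if (!"excitation" %in% names(df)) {
    warning("TSV has no excitation column; assuming all-green excitation")
    df$excitation <- "green"
  }
  ids <- unique(df$trace_id)
  traces <- lapply(ids, function(id) {
    d <- df[df$trace_id == id, ]
    d <- d[order(d$frame), ]
    meta <- if (length(metas) >= id && !is.null(metas[[id]])) metas[[id]] else list()
    intensity_trace(d$donor, d$acceptor, d$excitation, dt, meta)
  })
  trace_set(traces)
}

# -- legacy interleaved binary dialect ---------------------------------------

write_traces_legacy <- function(traces, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n_frames <- if (length(traces)) length(traces[[1]]$donor) else 0L
  writeBin(as.integer(n_frames), con, size = 4, endian = "little")
  writeBin(as.integer(2L * length(traces)), con, size = 2, endian = "little")
  if (length(traces)) {
    # frame-major: for each frame, all channels (donor then acceptor per trace)
    M <- matrix(0L, nrow = 2L * length(traces), ncol = n_frames)
    for (i in seq_along(traces)) {
      M[2L * i - 1L, ] <- as.integer(round(traces[[i]]$donor))
      M[2L * i, ] <- as.integer(round(traces[[i]]$acceptor))
    }
    writeBin(as.integer(as.vector(M)), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_traces_legacy <- function(path, frame_interval_s = 0.1) {
  con <- file(path, "rb")
  on.exit(close(con))
  n_frames <- readBin(con, "integer", 1, size = 4, endian = "little")
  n_channels <- readBin(con, "integer", 1, size = 2, endian = "little")
  if (length(n_frames) != 1L || length(n_channels) != 1L || n_frames < 0 ||
      n_channels < 0 || n_channels %% 2L != 0L)
    stop("malformed legacy .traces header (offset 0-5) in ", path)
  if (n_channels == 0L) return(trace_set(list()))
  body <- readBin(con, "integer", n_frames * n_channels, size = 2,
                  signed = TRUE, endian = "little")
  if (length(body) != n_frames * n_channels)
    stop("truncated legacy .traces body at offset ",
         6 + 2 * length(body), " in ", path)
  M <- matrix(body, nrow = n_channels, ncol = n_frames)
  traces <- lapply(seq_len(n_channels %/% 2L), function(i)
    intensity_trace(M[2L * i - 1L, ], M[2L * i, ],
                    frame_interval_s = frame_interval_s))
  trace_set(traces)
}
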