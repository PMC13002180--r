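#' Recording container
#'
#' A recording holds a channels x samples voltage matrix in microvolts, its
#' sampling rate, the probe geometry it was acquired on, and a per-channel
#' dead mask (channels replaced by noise through degradation or declared
#' dead by the user).
#'
#' @param traces numeric matrix, channels x samples, microvolts. Row order
#'   must match `geometry$channel_ids`.
#' @param sampling_rate sampling rate in Hz.
#' @param geometry an `slx_probe`.
#' @param dead_mask logical vector, one entry per channel; defaults to all
#'   `FALSE`.
#' @return an object of class `slx_recording`.
#' @export
new_recording <- function(traces, sampling_rate, geometry,
                          dead_mask = NULL) {
  traces <- as.matrix(traces)
  storage.mode(traces) <- "double"
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be > 0", call. = FALSE)
  if (nrow(traces) != n_channels(geometry))
    stop("traces row count must equal geometry channel count", call. = FALSE)
  dead_mask <- dead_mask %||% rep(FALSE, nrow(traces))
  if (length(dead_mask) != nrow(traces))
    stop("dead_mask length must equal channel count", call. = FALSE)
  structure(list(traces = traces,
                 sampling_rate = as.double(sampling_rate),
                 geometry = geometry,
                 dead_mask = as.logical(dead_mask),
                 duration = ncol(traces) / sampling_rate),
            class = "slx_recording")
}

#' @export
print.slx_recording <- function(x, ...) {
  cat(sprintf(
    "<slx_recording> %d ch x %d samples (%.3f s @ %g Hz), %d dead\n",
    nrow(x$traces), ncol(x$traces), x$duration, x$sampling_rate,
    sum(x$dead_mask)))
  invisible(x)
}

#' Read / write recordings as flat binary + JSON sidecar
#'
#' Traces are stored channel-major (all samples of channel 1, then channel
#' 2, ...) as little-endian float32. The sidecar `<prefix>.json` records
#' sampling rate, dimensions, dtype, the geometry file path and the dead
#' mask; the geometry itself is written next to the binary as
#' `<prefix>.geometry.csv`.
#'
#' @param recording an `slx_recording`.
#' @param prefix output path prefix (files `<prefix>.bin`, `<prefix>.json`,
#'   `<prefix>.geometry.csv` are created).
#' @return `write_recording()` returns `prefix` invisibly;
#'   `read_recording()` returns an `slx_recording` (float32 precision).
#' @export
write_recording <- function(recording, prefix) {
  bin <- paste0(prefix, ".bin")
  geo <- paste0(prefix, ".geometry.csv")
  write_geometry(recording$geometry, geo)
  con <- file(bin, "wb")
  on.exit(close(con))
  # channel-major: transpose so each channel's samples are contiguous
  writeBin(as.vector(t(recording$traces)), con, size = 4L,
           endian = "little")
  jsonlite::write_json(list(
    sampling_rate = recording$sampling_rate,
    n_channels = nrow(recording$traces),
    n_samples = ncol(recording$traces),
    dtype = "float32",
    order = "channel_major",
    geometry_file = basename(geo),
    dead_mask = recording$dead_mask
  ), paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  if (!identical(meta$dtype, "float32"))
    stop("unsupported dtype: ", meta$dtype, call. = FALSE)
  geometry <- read_geometry(file.path(dirname(paste0(prefix, ".json")),
                                      meta$geometry_file))
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  n <- meta$n_channels * meta$n_samples
  v <- readBin(con, what = "numeric", n = n, size = 4L, endian = "little")
  traces <- t(matrix(v, nrow = meta$n_samples, ncol = meta$n_channels))
  new_recording(traces, meta$sampling_rate, geometry,
                dead_mask = meta$dead_mask)
}
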