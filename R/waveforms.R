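#' Waveform extraction and templates
#'
#' Spike snippets are cut from a (preprocessed) recording at known
#' ground-truth spike times — the package deliberately has no spike
#' detector, so benchmark results are not confounded by sorting errors.
#' The per-neuron template is the element-wise median across that
#' neuron's aligned snippets, and the per-channel peak-to-peak amplitude
#' of a waveform (max minus min over time) is the feature every
#' localizer consumes.
#'
#' @name waveforms
NULL

#' Extract per-spike snippets
#'
#' Cuts a fixed temporal window around each spike time: `pre_ms` before to
#' `post_ms` after, so at 30 kHz the default 1/2 ms window is 90 samples
#' with the spike (trough) at sample 31. Spikes too close to the recording
#' edges are dropped and counted.
#'
#' @param recording an `slx_recording`.
#' @param spike_times spike times in seconds.
#' @param pre_ms,post_ms window before/after the spike time, ms.
#' @param unit_id optional unit id carried through to the result.
#' @return an `slx_waveforms` object: `snippets` (spikes x channels x
#'   samples array), `alignment_sample`, `window`, `sampling_rate`,
#'   `channel_ids`, `n_dropped`, `unit_id`.
#' @export
extract_snippets <- function(recording, spike_times, pre_ms = 1,
                             post_ms = 2, unit_id = NA_integer_) {
  fs <- recording$sampling_rate
  pre <- as.integer(round(pre_ms / 1000 * fs))
  post <- as.integer(round(post_ms / 1000 * fs))
  nsmp <- ncol(recording$traces)
  nch <- nrow(recording$traces)
  centers <- as.integer(round(spike_times * fs)) + 1L
  ok <- centers - pre >= 1L & centers + post - 1L <= nsmp
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " spike(s) too close to recording edges dropped")
  centers <- centers[ok]
  L <- pre + post
  snips <- array(0, dim = c(length(centers), nch, L))
  for (i in seq_along(centers)) {
    snips[i, , ] <- recording$traces[
      , (centers[i] - pre):(centers[i] + post - 1L), drop = FALSE]
  }
  structure(list(unit_id = unit_id, snippets = snips,
                 window = c(pre_ms = pre_ms, post_ms = post_ms),
                 alignment_sample = pre + 1L,
                 sampling_rate = fs,
                 channel_ids = recording$geometry$channel_ids,
                 n_dropped = n_dropped),
            class = "slx_waveforms")
}

#' @export
print.slx_waveforms <- function(x, ...) {
  d <- dim(x$snippets)
  cat(sprintf("<slx_waveforms unit %s> %d spikes x %d ch x %d samples\n",
              x$unit_id, d[1], d[2], d[3]))
  invisible(x)
}

#' Align snippets on their extremum
#'
#' Shifts each snippet by an integer number of samples so that its global
#' extremum — the largest absolute amplitude, evaluated on the peak
#' channel of a preliminary mean template — sits at the alignment sample,
#' reducing temporal jitter before the median template is taken.
#' Extracellular spikes are trough-dominated, so `mode = "extremum"`
#' effectively aligns on the trough; `"trough"`/`"peak"` force the sign.
#' Shifts are bounded by `max_jitter_ms`; samples shifted in from outside
#' the window are zero. Idempotent.
#'
#' @param ws an `slx_waveforms`.
#' @param max_jitter_ms maximum shift, ms.
#' @param mode extremum convention.
#' @return the aligned `slx_waveforms`.
#' @export
align_to_trough <- function(ws, max_jitter_ms = 0.5,
                            mode = c("extremum", "trough", "peak")) {
  mode <- match.arg(mode)
  d <- dim(ws$snippets)
  if (d[1] == 0L) return(ws)
  jit <- as.integer(round(max_jitter_ms / 1000 * ws$sampling_rate))
  # peak channel of the preliminary mean template
  mean_tpl <- apply(ws$snippets, c(2, 3), mean)
  ptp <- matrixStats::rowMaxs(mean_tpl) - matrixStats::rowMins(mean_tpl)
  pc <- which.max(ptp)
  a <- ws$alignment_sample
  lo <- max(1L, a - jit)
  hi <- min(d[3], a + jit)
  for (i in seq_len(d[1])) {
    seg <- ws$snippets[i, pc, lo:hi]
    idx <- switch(mode,
                  extremum = which.max(abs(seg)),
                  trough = which.min(seg),
                  peak = which.max(seg))
    shift <- (lo + idx - 1L) - a   # >0: extremum late, shift left
    if (shift == 0L) next
    s <- ws$snippets[i, , , drop = FALSE]
    new <- array(0, dim = c(1, d[2], d[3]))
    if (shift > 0)
      new[1, , 1:(d[3] - shift)] <- s[1, , (shift + 1):d[3]]
    else
      new[1, , (1 - shift):d[3]] <- s[1, , 1:(d[3] + shift)]
    ws$snippets[i, , ] <- new
  }
  ws
}

#' Median template of a waveform set
#'
#' Element-wise median over spikes, with per-channel peak-to-peak
#' amplitudes and the peak channel (ties broken toward the lowest channel
#' id).
#'
#' @param ws an `slx_waveforms` with at least one snippet.
#' @return an `slx_template`: `unit_id`, `waveform` (channels x samples),
#'   `ptp` (named per-channel vector), `peak_channel`, `channel_ids`.
#' @export
compute_template <- function(ws) {
  d <- dim(ws$snippets)
  if (d[1] == 0L)
    stop("cannot compute a template from an empty waveform set",
         call. = FALSE)
  wf <- matrix(0, nrow = d[2], ncol = d[3])
  for (ch in seq_len(d[2])) {
    wf[ch, ] <- matrixStats::colMedians(
      matrix(ws$snippets[, ch, ], nrow = d[1]))
  }
  rownames(wf) <- as.character(ws$channel_ids)
  ptp <- ptp_vector(wf)
  structure(list(unit_id = ws$unit_id, waveform = wf, ptp = ptp,
                 peak_channel = ws$channel_ids[which.max(ptp)],
                 channel_ids = ws$channel_ids),
            class = "slx_template")
}

#' Per-channel peak-to-peak amplitudes
#'
#' `ptp[j] = max_t w_j(t) - min_t w_j(t)`, the voltage difference between
#' peak and trough on each channel. Channels marked dead or anomalous are
#' *absent* from the result rather than zero: downstream localizers treat
#' them as nonexistent electrodes, which (unlike a zero weight) does not
#' bias the center-of-mass toward surviving channels.
#'
#' @param waveform channels x samples matrix with channel ids as rownames
#'   (or an `slx_template`).
#' @param exclude channel ids to report as absent.
#' @return named nonnegative vector over the present channels (possibly
#'   empty).
#' @export
ptp_vector <- function(waveform, exclude = NULL) {
  if (inherits(waveform, "slx_template")) waveform <- waveform$waveform
  if (ncol(waveform) < 1L) stop("waveform needs >= 1 sample", call. = FALSE)
  v <- matrixStats::rowMaxs(waveform) - matrixStats::rowMins(waveform)
  names(v) <- rownames(waveform)
  if (!is.null(exclude))
    v <- v[!(names(v) %in% as.character(exclude))]
  v
}

#' Matched-filter per-channel amplitudes
#'
#' Projects every channel's waveform onto a unit-norm temporal reference
#' (by default the waveform of the peak channel), yielding a signed
#' amplitude estimate per channel, clipped below at 0. Unlike the
#' peak-to-peak amplitude, the projection of zero-mean noise is itself
#' zero-mean, so channels carrying only noise contribute ~nothing instead
#' of a positive bias — the property that makes waveform-domain grid
#' convolution robust to dead electrodes.
#'
#' @param waveform channels x samples matrix (or an `slx_template`).
#' @param reference temporal reference vector (length = samples); default
#'   is the row of `waveform` with the largest peak-to-peak amplitude.
#' @return named nonnegative amplitude vector (uV-scale: the projection is
#'   divided by the reference's norm so a channel equal to `reference`
#'   returns its own L2 norm).
#' @export
matched_amplitudes <- function(waveform, reference = NULL) {
  if (inherits(waveform, "slx_template")) waveform <- waveform$waveform
  if (is.null(reference)) {
    ptp <- matrixStats::rowMaxs(waveform) - matrixStats::rowMins(waveform)
    reference <- waveform[which.max(ptp), ]
  }
  nrm <- sqrt(sum(reference^2))
  if (nrm == 0) stop("degenerate (all-zero) reference waveform",
                     call. = FALSE)
  a <- as.vector(waveform %*% (reference / nrm))
  a[a < 0] <- 0
  names(a) <- rownames(waveform)
  a
}

#' Write a waveform set or template to a directory
#'
#' Layout: little-endian float32 arrays (`snippets.bin` spikes-major or
#' `waveform.bin` channel-major) plus a `manifest.json` describing shapes,
#' dtype, window and channel ids.
#'
#' @param x an `slx_waveforms` or `slx_template`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_waveforms <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(x, "slx_template")) {
    con <- file(file.path(dir, "waveform.bin"), "wb")
    writeBin(as.vector(t(x$waveform)), con, size = 4L, endian = "little")
    close(con)
    manifest <- list(kind = "template", unit_id = x$unit_id,
                     shape = dim(x$waveform), dtype = "float32",
                     order = "channel_major",
                     channel_ids = x$channel_ids,
                     peak_channel = x$peak_channel)
  } else {
    con <- file(file.path(dir, "snippets.bin"), "wb")
    writeBin(as.vector(aperm(x$snippets, c(3, 2, 1))), con, size = 4L,
             endian = "little")
    close(con)
    manifest <- list(kind = "waveforms", unit_id = x$unit_id,
                     shape = dim(x$snippets), dtype = "float32",
                     order = "spike_channel_sample",
                     window = as.list(x$window),
                     alignment_sample = x$alignment_sample,
                     sampling_rate = x$sampling_rate,
                     channel_ids = x$channel_ids)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
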