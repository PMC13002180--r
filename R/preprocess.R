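#' Butterworth bandpass design (second-order sections)
#'
#' Designs a digital Butterworth bandpass of the given order via the
#' classic analog-prototype -> bandpass transform -> bilinear route and
#' returns it as cascaded biquads, the numerically stable form for the
#' 10th-order polynomial a 5th-order bandpass expands to. The passband
#' magnitude is normalised to 1 at the (prewarped) geometric centre
#' frequency, where a Butterworth bandpass is exactly flat.
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param fs sampling rate in Hz.
#' @param order filter order (of the lowpass prototype; the bandpass is
#'   2 x `order`).
#' @return numeric matrix `order` x 6, columns (b0, b1, b2, a0, a1, a2)
#'   with a0 = 1.
#' @export
butter_bandpass_sos <- function(low_hz, high_hz, fs, order = 5L) {
  if (!(0 < low_hz && low_hz < high_hz))
    stop("need 0 < low_hz < high_hz", call. = FALSE)
  if (high_hz >= fs / 2)
    stop("high_hz must be below the Nyquist frequency (", fs / 2, " Hz)",
         call. = FALSE)
  k <- 2 * fs
  w1 <- k * tan(pi * low_hz / fs)   # prewarped edges (rad/s)
  w2 <- k * tan(pi * high_hz / fs)
  B <- w2 - w1
  w0sq <- w1 * w2

  # analog lowpass prototype poles on the unit circle, left half-plane
  theta <- pi / 2 + pi * (2 * seq_len(order) - 1) / (2 * order)
  proto <- complex(modulus = 1, argument = theta)

  # each prototype pole p maps to the two roots of s^2 - B p s + w0^2
  bp_roots <- function(p) {
    disc <- sqrt(as.complex((B * p)^2 - 4 * w0sq))
    c((B * p + disc) / 2, (B * p - disc) / 2)
  }

  sections <- list()
  for (p in proto[Im(proto) > 1e-12]) {
    for (s in bp_roots(p)) sections <- c(sections, list(c(s, Conj(s))))
  }
  if (order %% 2 == 1) {
    r <- bp_roots(proto[which.min(abs(Im(proto)))])
    sections <- c(sections, list(r))  # conjugate pair or two real poles
  }

  bilinear <- function(s) (k + s) / (k - s)
  sos <- t(vapply(sections, function(pp) {
    z <- bilinear(pp)
    c(1, 0, -1, 1, -Re(z[1] + z[2]), Re(z[1] * z[2]))
  }, numeric(6)))

  # unity gain at the prewarped centre frequency
  f0 <- atan(sqrt(w0sq) / k) * fs / pi
  g <- abs(sos_response(sos, f0, fs))
  sos[1, 1:3] <- sos[1, 1:3] / g
  sos
}

#' Frequency response of a second-order-section cascade
#'
#' Evaluates the exact transfer function H(e^{i 2 pi f / fs}) analytically,
#' section by section.
#'
#' @param sos matrix as returned by [butter_bandpass_sos()].
#' @param f frequencies in Hz (vectorised).
#' @param fs sampling rate in Hz.
#' @return complex vector of responses (take `abs()` for magnitude).
#' @export
sos_response <- function(sos, f, fs) {
  zi <- exp(-2i * pi * f / fs)   # z^-1
  h <- rep(1 + 0i, length(f))
  for (s in seq_len(nrow(sos))) {
    h <- h * (sos[s, 1] + sos[s, 2] * zi + sos[s, 3] * zi^2) /
      (sos[s, 4] + sos[s, 5] * zi + sos[s, 6] * zi^2)
  }
  h
}

#' Causal Butterworth bandpass filter
#'
#' Filters every channel forward-only (causal, zero initial conditions)
#' through a 300-3,000 Hz fifth-order Butterworth bandpass by default, the
#' standard spike-band filter. An acausal (forward-backward, zero-phase)
#' option exists but is off by default, matching a real-time pipeline.
#'
#' @param recording an `slx_recording`.
#' @param low_hz,high_hz,order filter parameters.
#' @param acausal if `TRUE`, filter forward then backward (zero phase).
#' @return a filtered `slx_recording` (same dimensions and dead mask).
#' @export
bandpass <- function(recording, low_hz = 300, high_hz = 3000, order = 5L,
                     acausal = FALSE) {
  sos <- butter_bandpass_sos(low_hz, high_hz, recording$sampling_rate,
                             order)
  y <- sosfilt_matrix(sos, recording$traces)
  if (acausal)
    y <- sosfilt_matrix(sos, y[, rev(seq_len(ncol(y))), drop = FALSE])[
      , rev(seq_len(ncol(y))), drop = FALSE]
  new_recording(y, recording$sampling_rate, recording$geometry,
                dead_mask = recording$dead_mask)
}

#' Common median reference
#'
#' Subtracts, at every sample, the median across channels from every
#' channel, removing shared-mode noise. Idempotent; with an odd channel
#' count the per-sample cross-channel median of the output is exactly 0
#' (with an even count it is 0 up to one floating-point rounding of the
#' two-middle-value average).
#'
#' @param recording an `slx_recording` with at least 2 channels.
#' @return the referenced `slx_recording`.
#' @export
common_median_reference <- function(recording) {
  if (nrow(recording$traces) < 2L)
    stop("common median reference needs >= 2 channels", call. = FALSE)
  y <- subtract_column_medians(recording$traces)
  new_recording(y, recording$sampling_rate, recording$geometry,
                dead_mask = recording$dead_mask)
}

#' Detect anomalous channels
#'
#' A simplified two-test version of the coherence + power-distribution
#' protocol used on high-density probes:
#' \describe{
#'   \item{coherence}{a channel is `anomalous_coherence` when its maximum
#'     Pearson correlation with its `k_neighbors` nearest geometric
#'     neighbours, computed on a bandpassed analysis chunk, falls below
#'     `coherence_threshold`. Meaningful when channels share signal
#'     (tissue LFP or dense units); set the threshold to `NA` to disable,
#'     e.g. on synthetic data with spatially uncorrelated noise.}
#'   \item{power}{a channel is `anomalous_power` when the robust z-score
#'     (median/MAD) of its log band power in `psd_band` exceeds
#'     `psd_z_threshold`. One-sided (high power = noise-contaminated) by
#'     default: a two-sided test inverts once anomalous channels become
#'     the majority, flagging the surviving good channels instead.}
#' }
#' Channels listed in `declared_dead` are labelled `declared_dead` and
#' excluded from neighbour sets and robust statistics. Flags are invariant
#' to a global gain applied to all channels.
#'
#' @param recording an `slx_recording` (raw or preprocessed; the analysis
#'   chunk is bandpassed to `psd_band` internally).
#' @param coherence_threshold absolute correlation threshold (default 0.2;
#'   `NA` disables the test).
#' @param k_neighbors neighbours per channel for the coherence test.
#' @param psd_band c(low, high) Hz band for the power test.
#' @param psd_z_threshold robust z threshold (default 4).
#' @param two_sided flag low-power outliers as well.
#' @param declared_dead channel ids known dead (e.g. from a degradation
#'   plan or user input); `NULL` uses the recording's dead mask.
#' @param chunk_s analysis window length in seconds (default 1; a shorter
#'   recording is used whole with a warning).
#' @return an `slx_channel_status` data.frame with columns `channel_id`,
#'   `label` (one of good, anomalous_coherence, anomalous_power,
#'   declared_dead), `max_neighbor_corr`, `power_z`.
#' @export
detect_anomalous_channels <- function(recording,
                                      coherence_threshold = 0.2,
                                      k_neighbors = 4L,
                                      psd_band = c(300, 3000),
                                      psd_z_threshold = 4,
                                      two_sided = FALSE,
                                      declared_dead = NULL,
                                      chunk_s = 1) {
  coherence_threshold <- coherence_threshold %||% NA
  g <- recording$geometry
  nch <- n_channels(g)
  ns_chunk <- min(ncol(recording$traces),
                  as.integer(round(chunk_s * recording$sampling_rate)))
  if (recording$duration < chunk_s)
    warning("recording shorter than the analysis window; using all of it")
  if (is.null(declared_dead))
    declared_dead <- g$channel_ids[recording$dead_mask]
  dead_idx <- channel_index(g, declared_dead)
  alive <- setdiff(seq_len(nch), dead_idx)

  chunk <- recording$traces[, seq_len(ns_chunk), drop = FALSE]
  sos <- butter_bandpass_sos(psd_band[1], psd_band[2],
                             recording$sampling_rate)
  chunk <- sosfilt_matrix(sos, chunk)

  label <- rep("good", nch)
  label[dead_idx] <- "declared_dead"
  power_z <- rep(NA_real_, nch)
  max_corr <- rep(NA_real_, nch)

  if (length(alive) >= 2L && ns_chunk >= 4L) {
    # power-distribution test
    logp <- log(matrixStats::rowVars(chunk))
    med <- median(logp[alive])
    s <- mad(logp[alive], center = med)
    if (s > 0) {
      power_z[alive] <- (logp[alive] - med) / s
      bad_p <- if (two_sided) abs(power_z) > psd_z_threshold
               else power_z > psd_z_threshold
      label[alive][bad_p[alive]] <- "anomalous_power"
    }
    # coherence test
    if (!is.na(coherence_threshold)) {
      pos <- g$positions[alive, , drop = FALSE]
      d <- cross_dist(pos, pos)
      cc <- cor(t(chunk[alive, , drop = FALSE]))
      for (i in seq_along(alive)) {
        nb <- order(d[i, ])[-1]
        nb <- nb[seq_len(min(k_neighbors, length(nb)))]
        max_corr[alive[i]] <- max(cc[i, nb])
      }
      bad_c <- !is.na(max_corr) & max_corr < coherence_threshold &
        label == "good"
      label[bad_c] <- "anomalous_coherence"
    }
  } else {
    warning("degenerate input (too few live channels or samples); ",
            "all live channels labelled good")
  }

  structure(data.frame(channel_id = g$channel_ids, label = label,
                       max_neighbor_corr = max_corr, power_z = power_z),
            class = c("slx_channel_status", "data.frame"))
}

#' Write a channel-status table to CSV
#'
#' @param status an `slx_channel_status`.
#' @param path output CSV path (columns `channel_id,label`).
#' @return `path`, invisibly.
#' @export
write_channel_status <- function(status, path) {
  write.csv(status[, c("channel_id", "label")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
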