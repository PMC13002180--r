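#' Synthetic ground-truth recordings
#'
#' The generator emulates a standard simulated benchmarking setup for
#' spike source localization on a high-density planar probe: point-source
#' neurons at known positions, Poisson spike trains, a canonical biphasic
#' extracellular waveform whose per-channel amplitude follows a monopole
#' 1/distance decay, a slight per-spike lognormal amplitude modulation,
#' and uncorrelated Gaussian background noise (10 uV by default) at
#' 30 kHz. Because the forward model is an exact monopole, the spatial
#' amplitude structure the localizers consume is controlled analytically,
#' which is what the package's tests exploit.
#'
#' @name simulate
NULL

# Canonical biphasic extracellular spike: negative trough followed by a
# smaller positive peak, ~2 ms total, normalised so its sampled
# peak-to-peak amplitude is exactly 1. Shape parameters vary per unit.
canonical_waveform <- function(sampling_rate,
                               trough_width_ms = 0.25,
                               peak_width_ms = 0.45,
                               peak_delay_ms = 0.5,
                               peak_ratio = 0.35,
                               total_ms = 2) {
  dt <- 1000 / sampling_rate                     # ms per sample
  t <- seq(-total_ms / 2, total_ms / 2, by = dt) # trough at t = 0
  w <- -exp(-t^2 / (2 * trough_width_ms^2)) +
    peak_ratio * exp(-(t - peak_delay_ms)^2 / (2 * peak_width_ms^2))
  w <- w / (max(w) - min(w))
  list(samples = w, trough_index = which.min(w))
}

# Homogeneous Poisson train thinned by an absolute refractory period
# (later spike deleted). Assumes RNG already seeded by the caller.
poisson_train <- function(rate_hz, duration_s, refractory_ms) {
  if (duration_s <= 0) return(numeric(0))
  n <- rpois(1L, rate_hz * duration_s)
  if (n == 0L) return(numeric(0))
  t <- sort(runif(n, 0, duration_s))
  if (refractory_ms > 0 && length(t) > 1L) {
    keep <- logical(length(t))
    keep[1] <- TRUE
    last <- t[1]
    r <- refractory_ms / 1000
    for (i in 2:length(t)) {
      if (t[i] - last >= r) {
        keep[i] <- TRUE
        last <- t[i]
      }
    }
    t <- t[keep]
  }
  t
}

#' Sample ground-truth units
#'
#' Draws `n_neurons` point sources uniformly inside a spatial box next to
#' the probe, with lognormal base amplitudes (median 100 uV peak-to-peak at
#' the 20 um reference distance), per-unit waveform shape parameters, and
#' Poisson spike trains thinned by an absolute refractory period.
#'
#' @param geometry an `slx_probe`.
#' @param n_neurons number of units.
#' @param bounds list with elements `x`, `y`, `z`, each a length-2 range in
#'   um. Default: probe x-range padded by 20 um, probe y-range, z in
#'   \[10, 100\] um (neurons on the tissue side of the plane).
#' @param rate_hz mean firing rate (default 5 Hz).
#' @param duration_s recording duration the trains must fit in.
#' @param refractory_ms absolute refractory period (default 2 ms; the later
#'   spike of a violating pair is deleted).
#' @param amplitude_median_uv,amplitude_sdlog lognormal base-amplitude
#'   parameters (peak-to-peak uV at the reference distance).
#' @param min_peak_uv minimum clean peak-to-peak amplitude on the nearest
#'   channel (uV); a (position, amplitude) draw below it is rejected and
#'   redrawn, emulating the minimum-amplitude constraint extracellular
#'   simulators apply when placing neurons. 0 disables.
#' @param d_ref reference distance of the base amplitude, um (must match
#'   [render_recording()]).
#' @param seed integer seed; identical inputs + seed give identical units.
#' @return list of `slx_unit` objects (fields `unit_id`, `position`,
#'   `base_amplitude`, `spike_times`, `shape`), with `duration_s` attached
#'   as an attribute.
#' @export
sample_ground_truth <- function(geometry, n_neurons, bounds = NULL,
                                rate_hz = 5, duration_s = 30,
                                refractory_ms = 2,
                                amplitude_median_uv = 100,
                                amplitude_sdlog = 0.4,
                                min_peak_uv = 50, d_ref = 20,
                                seed = 0L) {
  pos <- geometry$positions
  z0 <- pos[1, 3]
  bounds <- bounds %||% list(x = range(pos[, 1]) + c(-20, 20),
                             y = range(pos[, 2]),
                             z = z0 + c(10, 100))
  for (ax in c("x", "y", "z")) {
    b <- bounds[[ax]]
    if (is.null(b) || length(b) != 2L || b[2] < b[1])
      stop("empty or invalid bounds for axis ", ax, call. = FALSE)
  }
  if (bounds$z[1] < z0)
    stop("bounds$z must lie on or above the probe plane (z >= ",
         z0, ")", call. = FALSE)
  with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      repeat {
        p <- c(runif(1, bounds$x[1], bounds$x[2]),
               runif(1, bounds$y[1], bounds$y[2]),
               runif(1, bounds$z[1], bounds$z[2]))
        amp <- rlnorm(1, meanlog = log(amplitude_median_uv),
                      sdlog = amplitude_sdlog)
        d_min <- min(dist_to_points(p, geometry$positions))
        if (d_min > 0 && amp * d_ref / d_min >= min_peak_uv) break
      }
      shape <- list(trough_width_ms = runif(1, 0.15, 0.35),
                    peak_width_ms = runif(1, 0.3, 0.6),
                    peak_delay_ms = runif(1, 0.4, 0.7),
                    peak_ratio = runif(1, 0.2, 0.5))
      st <- poisson_train(rate_hz, duration_s, refractory_ms)
      structure(list(unit_id = i, position = p, base_amplitude = amp,
                     spike_times = st, shape = shape),
                class = "slx_unit")
    }) -> units
    attr(units, "duration_s") <- duration_s
    units
  })
}

# Clean per-channel peak-to-peak amplitudes of a unit: monopole decay from
# the source, base_amplitude referenced at d_ref.
unit_amplitudes <- function(unit, geometry, d_ref = 20, decay_power = 1) {
  d <- dist_to_points(unit$position, geometry$positions)
  if (any(d == 0))
    stop("neuron coincides with an electrode (distance 0): ",
         "singular decay", call. = FALSE)
  unit$base_amplitude * (d_ref / d)^decay_power
}

#' Render a voltage recording from ground-truth units
#'
#' Each spike adds, on every channel, the unit's canonical waveform scaled
#' by `base_amplitude * (d_ref / distance)^decay_power` and by a per-spike
#' lognormal modulation factor of mean 1 and coefficient of variation
#' `amp_modulation_cv`. I.i.d. Gaussian noise of `noise_std` uV is added to
#' every sample. The waveform trough lands on the spike time.
#'
#' @param units list of `slx_unit` (may be empty for a noise-only
#'   recording).
#' @param geometry an `slx_probe`.
#' @param duration_s recording length; defaults to the `duration_s`
#'   attribute carried by `units`.
#' @param noise_std background noise standard deviation in uV.
#' @param sampling_rate Hz.
#' @param amp_modulation_cv coefficient of variation of the per-spike
#'   amplitude modulation (0 disables it).
#' @param d_ref reference distance of `base_amplitude`, um.
#' @param decay_power amplitude decay exponent (1 = monopole, matching the
#'   triangulation model; values up to 2 supported for robustness
#'   experiments).
#' @param seed integer seed.
#' @return an `slx_recording` with a `clean_templates` attribute holding
#'   each unit's noise-free channels x samples template.
#' @export
render_recording <- function(units, geometry, duration_s = NULL,
                             noise_std = 10, sampling_rate = 30000,
                             amp_modulation_cv = 0.05, d_ref = 20,
                             decay_power = 1, seed = 0L) {
  duration_s <- duration_s %||% attr(units, "duration_s")
  if (is.null(duration_s))
    stop("duration_s not given and not carried by `units`", call. = FALSE)
  nch <- n_channels(geometry)
  nsmp <- as.integer(round(duration_s * sampling_rate))
  traces <- with_seed(child_seed(seed, 1L), {
    if (noise_std > 0)
      matrix(rnorm(nch * nsmp, sd = noise_std), nrow = nch)
    else
      matrix(0, nrow = nch, ncol = nsmp)
  })
  clean <- vector("list", length(units))
  if (length(units)) {
    mods_seed <- child_seed(seed, 2L)
    sdlog <- sqrt(log(1 + amp_modulation_cv^2))
    for (ui in seq_along(units)) {
      u <- units[[ui]]
      wf <- do.call(canonical_waveform,
                    c(list(sampling_rate = sampling_rate), u$shape))
      amps <- unit_amplitudes(u, geometry, d_ref, decay_power)
      clean[[ui]] <- outer(amps, wf$samples)
      rownames(clean[[ui]]) <- as.character(geometry$channel_ids)
      ns <- length(u$spike_times)
      if (ns == 0L) next
      mods <- if (amp_modulation_cv > 0)
        with_seed(child_seed(mods_seed, u$unit_id),
                  rlnorm(ns, meanlog = -sdlog^2 / 2, sdlog = sdlog))
      else rep(1, ns)
      L <- length(wf$samples)
      for (si in seq_len(ns)) {
        s0 <- as.integer(round(u$spike_times[si] * sampling_rate)) + 1L -
          (wf$trough_index - 1L)
        a <- max(1L, s0)
        b <- min(nsmp, s0 + L - 1L)
        if (a > b) next
        traces[, a:b] <- traces[, a:b] +
          mods[si] * clean[[ui]][, (a - s0 + 1L):(b - s0 + 1L)]
      }
    }
  }
  rec <- new_recording(traces, sampling_rate, geometry)
  names(clean) <- vapply(units, function(u) as.character(u$unit_id), "")
  attr(rec, "clean_templates") <- clean
  rec
}

#' Degrade a recording by killing electrodes
#'
#' Replaces `round(fraction * n_channels)` channels, chosen uniformly at
#' random under `seed`, with i.i.d. Gaussian noise of `noise_std` uV
#' (50 uV by default), mimicking electrodes that have lost functionality.
#' The choice is a seeded permutation truncated at the requested count, so
#' sweeping `fraction` upward under one seed yields *nested* dead sets:
#' level k's dead channels are a subset of level k+1's.
#'
#' @param recording an `slx_recording` with an all-false dead mask (unless
#'   `cumulative = TRUE`, in which case prior dead channels are kept and
#'   counted toward the target).
#' @param fraction fraction of channels to kill, in \[0, 1\].
#' @param noise_std replacement noise standard deviation, uV.
#' @param seed integer seed (one seed = one degradation pattern).
#' @param cumulative allow degrading an already-degraded recording.
#' @return list with elements `recording` (new `slx_recording`; the input
#'   is unmodified) and `plan` (an `slx_degradation_plan`: `fraction`,
#'   `dead_channels`, `noise_std`, `seed`).
#' @export
degrade <- function(recording, fraction, noise_std = 50, seed = 0L,
                    cumulative = FALSE) {
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  if (any(recording$dead_mask) && !cumulative)
    stop("recording already has dead channels; use cumulative = TRUE",
         call. = FALSE)
  g <- recording$geometry
  nch <- n_channels(g)
  n_dead <- as.integer(round(fraction * nch))
  perm <- with_seed(seed, sample(g$channel_ids))
  # keep previously dead channels at the front so cumulative sweeps nest
  if (cumulative) {
    prior <- g$channel_ids[recording$dead_mask]
    perm <- c(prior, setdiff(perm, prior))
    n_dead <- max(n_dead, length(prior))
  }
  dead <- perm[seq_len(n_dead)]
  plan <- structure(list(fraction = fraction, dead_channels = sort(dead),
                         noise_std = noise_std, seed = seed),
                    class = "slx_degradation_plan")
  traces <- recording$traces
  if (n_dead > 0) {
    idx <- channel_index(g, dead)
    noise <- with_seed(child_seed(seed, 3L),
                       matrix(rnorm(n_dead * ncol(traces),
                                    sd = noise_std), nrow = n_dead))
    traces[idx, ] <- noise
  }
  mask <- recording$dead_mask
  mask[channel_index(g, dead)] <- TRUE
  out <- new_recording(traces, recording$sampling_rate, g,
                       dead_mask = mask)
  list(recording = out, plan = plan)
}
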