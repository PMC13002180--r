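# Shared fixtures and small oracles, all built in code.

# single-column probe, 20 um pitch
column_probe <- function(n = 16, pitch = 20) {
  make_probe(n, layout = "single_column", y_pitch_um = pitch)
}

# exact monopole ptp footprint of a source at `src` with constant `cc`
monopole_ptp <- function(geometry, src, cc = 2000) {
  d <- sqrt(colSums((t(geometry$positions) - src)^2))
  stats::setNames(cc / d, geometry$channel_ids)
}

# point-in-convex-hull test for planar channel layouts (z ignored):
# all cross products against the hull edges must be on one side.
in_hull_xy <- function(pt, positions, tol = 1e-6) {
  xy <- positions[, 1:2, drop = FALSE]
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  n <- nrow(hull)
  if (n == 1L) return(sqrt(sum((pt[1:2] - hull[1, ])^2)) <= tol)
  if (n == 2L) {                      # degenerate hull: a segment
    a <- hull[1, ]; b <- hull[2, ]
    ab <- b - a; t <- sum((pt[1:2] - a) * ab) / sum(ab^2)
    t <- min(max(t, 0), 1)
    return(sqrt(sum((a + t * ab - pt[1:2])^2)) <= tol)
  }
  s <- vapply(seq_len(n), function(i) {
    a <- hull[i, ]; b <- hull[i %% n + 1L, ]
    (b[1] - a[1]) * (pt[2] - a[2]) - (b[2] - a[2]) * (pt[1] - a[1])
  }, 0)
  all(s >= -tol) || all(s <= tol)
}

# tiny ground-truth world used by pipeline smoke tests
tiny_world <- function(seed = 1, n_units = 5, duration_s = 5,
                       n_channels = 32) {
  g <- make_probe(n_channels)
  units <- sample_ground_truth(g, n_units, duration_s = duration_s,
                               seed = seed)
  rec <- render_recording(units, g, seed = seed + 100)
  list(geometry = g, units = units, recording = rec)
}

tiny_config <- function(...) {
  desk_config(
    probe = list(n_channels = 32L),
    simulate = list(n_neurons = 5L, duration_s = 5),
    benchmark = list(levels = c(0, 0.5), seeds = 0L),
    gridsearch = list(levels = c(0, 0.5), max_spikes_per_unit = 5L),
    ...)
}
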