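# spikeloc

Spike source localization on high-density extracellular probes, and
benchmarking of its robustness to electrode degradation.

When a neuron fires near a Neuropixels-class probe, the action potential
is visible on many electrodes at once, with amplitudes that fall off
with distance. `spikeloc` estimates the neuron's position
`p = (x, y, z)` (micrometres; probe plane at z = 0) from the
per-channel amplitude footprint `ptp_j` with the three estimators in
common use:

* **COM** — center of mass, `p = Σ_j ptp_j p_j / Σ_j ptp_j`: fast, but
  confined to the electrode array's convex hull and to z = 0;
* **MT** — monopolar triangulation: least-squares fit of a point source
  with inverse-distance decay, `ptp_j ≈ c / ‖p − p_j‖`, over
  `(x, y, z, c)` with local-radius and candidate-window regularization;
* **GC** — grid convolution: a dense lattice of candidate positions is
  scored by the similarity between the observed footprint and a
  distance-decay prototype footprint per node, and the top 5% of nodes
  are similarity-averaged.

Because chronic implants lose electrodes over time, the package also
ships a ground-truth simulator (point-source neurons, Poisson trains,
monopole amplitude decay, 10 µV noise at 30 kHz), an electrode
degradation model (a growing, nested fraction of channels replaced by
50 µV noise), the standard preprocessing chain (causal 300–3,000 Hz
order-5 Butterworth, common median reference, anomalous-channel
detection), ground-truth waveform/template extraction, and a benchmark
harness that sweeps degradation levels and scores accuracy, median
localization error and estimated drift per algorithm — reproducing, at
desk scale, the published comparison in which the physically detailed
MT wins on clean recordings while the simpler COM and the grid-bounded
GC are the more robust choices for long-term degraded recordings.

## Worked example

```r
library(spikeloc)

probe <- make_probe(96)                       # staggered 2-column probe
units <- sample_ground_truth(probe, n_neurons = 5, duration_s = 10,
                             seed = 42)
rec   <- render_recording(units, probe, seed = 42)
rec   <- common_median_reference(bandpass(rec))

u   <- units[[1]]                             # true position known
ws  <- align_to_trough(extract_snippets(rec, u$spike_times, unit_id = 1))
tpl <- compute_template(ws)

grid <- build_grid(probe)
localize_com(tpl$ptp, probe, radius_um = 75)
localize_mt(tpl$ptp, probe)
localize_gc(matched_amplitudes(tpl), probe, grid)
```

```
<slx_estimate COM> (19.96, 890.59, 0.00) um
<slx_estimate MT>  (49.56, 891.05, 26.49) um
<slx_estimate GC>  (54.42, 890.72, 42.42) um
```

The true position is (45.9, 890.2, 35.8) µm, so the errors are
COM 44.2 µm, MT 10.0 µm, GC 10.9 µm: COM is pinned to the probe plane
(z = 0) and pulled toward the array axis, while MT and GC use the
relative amplitudes to recover the off-plane position — the clean-regime
picture. Under heavy degradation the ordering inverts for MT; run the
sweep to see it:

```r
records <- run_degradation_sweep(desk_config())   # ~7 min, 1 CPU
subset(records, degradation_fraction %in% c(0, 0.9),
       select = c(seed, degradation_fraction, algorithm,
                  accuracy, median_error_um, drift_um))
```

## Command line

Every stage is scriptable via one dispatcher (exit codes: 0 ok,
1 runtime failure, 2 config error):

```sh
Rscript -e 'quit(status = spikeloc::cli())' simulate \
    --config config.json --seed 1 --out out/
Rscript -e 'quit(status = spikeloc::cli())' sweep \
    --config config.json --out out/sweep
```

Configs are JSON overlays on the full-scale preset (`slx_config()`);
`desk_config()` is the scaled preset used by the tests. Recordings are
flat float32 binaries with JSON sidecars; geometries CSV/JSON; ground
truth JSON; metrics tidy CSV.

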