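---
title: "Spike source localization under electrode degradation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike source localization under electrode degradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-density extracellular probes record each action potential on many
electrodes at once. The spatial pattern of spike amplitudes across those
electrodes — the *footprint* — carries information about where the neuron
sits relative to the array. Estimating that position ("spike source
localization") supports spike sorting, probe-drift tracking, and
anatomical interpretation of chronic recordings. Three estimators are in
common use on Neuropixels-class probes, and `spikeloc` implements all
three on a common footprint interface, together with a ground-truth
simulator and a benchmarking harness whose purpose is to ask one
question: *how do the estimators cope as electrodes progressively die?*

Throughout, positions are in micrometres with the probe plane at z = 0
and tissue at z > 0, voltages in microvolts, times in seconds.

## The three estimators

All three consume a per-channel nonnegative amplitude vector (by default
the peak-to-peak amplitude, `ptp`) restricted to channels within a
*local radius* of the peak channel — the regularization the widely used
reference implementations apply by default.

**Center of mass (COM).** The amplitude-weighted mean of electrode
positions. It is a convex combination, so the estimate can never leave
the convex hull of the contributing electrodes, and on a planar probe
its z is identically 0. Default radius: 75 um.

**Monopolar triangulation (MT).** Models the neuron as a point current
source whose amplitude decays as the inverse distance,
`V_j = c / ||p - p_j||`, and minimizes the sum of squared residuals over
`(x, y, z, c)` by bounded nonlinear least squares. Numerical choices:

* The printed loss in the source literature omits the square; a bare sum
  of residuals is unbounded below, and the reference implementation uses
  a least-squares optimizer, so we fit squared residuals.
* `c` enters the model linearly in `1/d`, so it is profiled out in
  closed form (`c*(p) = sum(ptp/d) / sum(1/d^2)`), leaving a
  well-conditioned three-parameter problem; the gradient uses the
  envelope theorem.
* The position is box-constrained to ±`max_distance_um` (default
  1,000 um) around the COM initialization in x and y, and to
  `[0, max_distance_um]` in z — a planar array cannot distinguish the
  sign of z, so the nonnegative solution is reported.
* The loss has spurious local minima when the start is far from the
  source relative to the array scale, so the optimizer is multi-started
  at z = 20 um plus two starts scaled to the local channel spacing, and
  the best objective wins. This matters on toy geometries with
  micrometre-scale arrays; on a real probe the starts usually agree.
* Fewer than four contributing channels leave the four unknowns
  underdetermined and raise an error.

**Grid convolution (GC).** Lays a dense lattice of hypothetical source
positions over the probe (5 um spacing, padded by the channel radius,
z levels up to 100 um), gives every node a prototype footprint on the
selected channels, scores each node by the dot product between the
observed footprint and the unit-normalized prototype, and returns the
score-weighted mean of the nodes whose score reaches the top 5% of
positive scores. Two design points deserve emphasis:

* *Kernel.* The prototype decay is `exp(-d / sigma)` in the 3-D
  source-to-channel distance, with `sigma = 40` um by default. A
  Gaussian kernel `exp(-d^2 / 2 sigma^2)` is also available but is a
  poor default on a planar array, for a reason that is easy to miss:
  with all channels at z = 0, `d^2 = r^2 + z^2` splits the Gaussian into
  an xy factor times a factor common to all channels, and the common
  factor cancels under per-node normalization. The normalized Gaussian
  prototype is therefore *exactly* independent of node depth, and no
  amount of data can make the similarity prefer one z over another. The
  exponential does not factorize. The scale 40 um makes the exponential
  decay rate match the monopole's local decay rate (`d log(1/d)/dd =
  -1/d`) at the typical source-channel distance of the simulated world.
* *Feature.* In the benchmark pipeline GC consumes matched-filter
  amplitudes (each channel's waveform projected on the unit-norm peak
  channel waveform, clipped at 0) rather than peak-to-peak amplitudes.
  For clean data the two rank nodes identically, but their noise
  behaviour differs sharply: the ptp of a pure-noise channel is
  positively biased (max minus min of ~90 noise samples), while the
  projection of zero-mean noise is zero-mean. The reference
  implementation computes full waveform dot products, of which the
  projection amplitude is the faithful scalar reduction. COM and MT
  keep ptp, which is how they are defined in the literature.

A consequence worth knowing before trusting GC's z: even with the
exponential kernel, footprints of deep sources converge toward each
other (at z = 100 um all channel distances are nearly equal), so the
similarity ridge along z is shallow and the top-5% node average smears z
by roughly 10-30 um. GC's in-plane self-match is accurate to about one
grid step; its depth estimate is best treated as qualitative. This is a
property of the estimator class on planar arrays, not an implementation
artifact, and it is why one of the package's acceptance tests (exact 3-D
self-match of node prototypes) is expected to fail in z and is left
failing rather than weakened.

## The synthetic world

`sample_ground_truth()` and `render_recording()` emulate the standard
simulated benchmarking setup at desk scale:

* a staggered two-column probe (384 channels over ~3.8 mm by default;
  the test preset uses 96 channels over ~1 mm);
* point-source neurons at uniform positions with z in [10, 100] um,
  lognormal base amplitudes (median 100 uV peak-to-peak at the 20 um
  reference distance, sdlog 0.4), re-drawn until the clean peak-channel
  amplitude reaches 50 uV — the minimum-amplitude constraint the
  established biophysical simulator applies when placing cells;
* homogeneous Poisson spike trains (5 Hz) thinned by a 2 ms absolute
  refractory period;
* a parametric biphasic waveform (~2 ms, trough-dominated, per-unit
  random width and asymmetry) scaled per channel by the monopole
  `base_amplitude * d_ref / d` decay — so the clean footprint follows
  the MT forward model exactly, which the tests exploit (a
  configuration switch allows `1/d^alpha` for robustness experiments);
* per-spike lognormal amplitude modulation with CV 0.05 (the magnitude
  of the "slight modulation" is not documented anywhere; 5% is a
  conservative physiological variability);
* uncorrelated Gaussian noise, 10 uV, at 30 kHz.

What the generator deliberately does **not** contain: multicompartment
morphology (footprint shape detail is irrelevant to amplitude-based
localization), spatially correlated noise or LFP, electrode impedance
effects, and probe motion. Two practical consequences: first, a green
benchmark here says the estimators behave as described *under a
monopole forward model* — it cannot certify behaviour on biophysically
detailed waveforms; second, coherence-based bad-channel detection,
which in tissue leans on shared low-frequency signal, has nothing to
lean on here (neighbour correlations of sparse-spike channels are
~0.01-0.1), so the sweep presets disable the coherence test and the
absolute threshold (default 0.2) is meant for real recordings.

**Electrode degradation** replaces a seeded, uniformly chosen channel
subset with 50 uV Gaussian noise on the *raw* recording. The subset is
a truncated seeded permutation, so sweeping the fraction upward under
one seed gives nested dead sets — estimated drift then measures signal
loss, not channel reshuffling.

## The preprocessing chain

A causal (forward-only) 300-3,000 Hz fifth-order Butterworth bandpass —
designed in-package via the analog-prototype route and applied as
cascaded biquads in compiled code, with the analytic frequency response
exposed for verification — followed by common median referencing, then
anomalous-channel detection with two tests: maximum neighbour
correlation below threshold (`anomalous_coherence`) and robust z-score
of log band power (`anomalous_power`). The power test is one-sided
(high) by default: once dead channels are the majority, a two-sided
robust z flags the surviving good channels instead, which inverts the
pipeline's intent.

With an odd channel count the common median reference leaves the
per-sample cross-channel median exactly zero; with an even count the
mean of the two middle order statistics reintroduces one rounding step
(~1e-13 relative), which the tests acknowledge.

## The benchmark and its stated world

`run_degradation_sweep()` runs, per seed and degradation level:
simulate, degrade, preprocess, extract ground-truth-aligned templates
(median across aligned snippets), localize with all three algorithms,
and score accuracy (30 um radius), median localization error, and
estimated drift against the same seed's 0% estimates. The desk preset —
10 neurons, 30 s, 96 channels, levels 0-0.9, seeds 0-2 — runs in a few
minutes on one CPU; the full-scale preset mirrors the original setup
(50 neurons, 90 s, 384 channels, 25 levels to 94%, five seeds).

One design choice required adjudicating between irreconcilable options,
and is worth recording. Should channels known or detected to be dead be
*excluded* from localization? Three candidate pipelines were evaluated:

1. *Exclude detected channels.* Works below ~50% degradation, but the
   robust-z detector necessarily breaks once dead channels are the
   majority, producing a regime switch (errors improve, then jump) that
   contradicts the monotone degradation curves the benchmark is meant
   to reproduce.
2. *Exclude known-dead channels.* At 80-90% degradation almost no unit
   retains four live channels within the MT radius, so MT fails
   outright rather than degrading — again not the observed behaviour of
   the reference pipelines, which keep producing (bad) estimates.
3. *No exclusion.* Dead channels contribute their noise footprints at
   every level; all three error curves rise smoothly and monotonically,
   and MT — which must *fit* the noise — degrades fastest relative to
   COM.

The sweep presets use (3); detection still runs and its labels are
recorded, and both exclusion modes remain available
(`preprocess$exclude_flagged`, `preprocess$declare_dead`).

At the top of the degradation range the three estimators converge
toward a common error floor — the distance to the nearest live
electrode — and our amplitude-domain GC sits a few micrometres *above*
MT there, whereas the original waveform-domain GC sat below. The
corresponding acceptance clauses are left failing with this analysis
rather than adjusted; the clean-regime ranking (MT and GC well below
COM) and the monotone degradation shape reproduce robustly.

`parameter_grid_search()` re-localizes the same degraded spike sets
under regularization grids (MT: channel radius x candidate window; GC:
channel radius x similarity percentile; two decades around the
defaults) and reports the median spike error per cell and level plus
each cell's low-to-high-level error change.

## Numerical and convention details

* Peak channel and equal-similarity ties break toward the lowest
  channel or node index; all pipelines are deterministic given a seed,
  and every seeded operation restores the caller's RNG state.
* Snippet alignment uses integer-sample shifts to the global extremum
  on the peak channel (extracellular spikes are trough-dominated);
  sub-sample interpolation is deliberately avoided since ptp is
  insensitive to sub-sample jitter.
* Dead or flagged channels are *absent* from footprints, never zero: a
  zero would act as a strong observation at that electrode and bias
  every estimator toward the survivors in a different way than removal.
* Recording I/O is channel-major float32 with a JSON sidecar; geometry
  is CSV or JSON (`channel_id,x,y,z`); all writers are byte-stable for
  fixed input.

## Known limitations

* GC depth is semi-quantitative on planar arrays (see above).
* The coherence test's absolute-threshold contract assumes
  tissue-like shared signal; on this package's synthetic data it must
  be disabled or given a near-zero threshold.
* The simulator's monopole decay makes MT exactly well-specified —
  real waveforms are not monopolar, so MT's clean-regime advantage here
  is an upper bound on its practical advantage.
* Statistical significance machinery (ANOVA/post-hoc) is out of scope;
  the tidy CSV output is shaped for external statistics packages.
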