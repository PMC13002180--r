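test_that("bandpass removes DC, passes 1 kHz, and rejects 60 Hz", {
  fs <- 30000
  t <- (0:29999) / fs
  g <- make_probe(4)
  rec <- new_recording(rbind(100 + 0 * t,
                             50 * sin(2 * pi * 1000 * t),
                             50 * sin(2 * pi * 60 * t),
                             0 * t), fs, g)
  out <- bandpass(rec)
  late <- 20000:30000                        # past the causal transient
  expect_lt(abs(mean(out$traces[1, late])), 0.1)
  amp1k <- diff(range(out$traces[2, late])) / 2
  expect_lt(abs(20 * log10(amp1k / 50)), 1)  # within 1 dB in passband
  amp60 <- diff(range(out$traces[3, late])) / 2
  expect_lte(20 * log10(amp60 / 50), -40)    # >= 40 dB attenuation
  expect_identical(dim(out$traces), dim(rec$traces))
})

test_that("the designed filter's analytic response matches Butterworth", {
  sos <- butter_bandpass_sos(300, 3000, 30000, 5)
  h <- abs(sos_response(sos, c(60, 300, 949, 1000, 3000), 30000))
  # band edges at -3 dB, flat passband, steep low-frequency skirt
  # (reference values cross-checked against scipy.signal.butter)
  expect_equal(20 * log10(h[1]), -74.16, tolerance = 0.01)
  expect_equal(20 * log10(h[2]), -3.01, tolerance = 0.02)
  expect_equal(h[3], 1, tolerance = 1e-9)    # geometric centre: exact 1
  expect_equal(20 * log10(h[4]), 0, tolerance = 1e-6)
  expect_equal(20 * log10(h[5]), -3.01, tolerance = 0.02)
  expect_error(butter_bandpass_sos(300, 15000, 30000), "Nyquist")
})

test_that("common median reference satisfies its exact contracts", {
  g3 <- probe_geometry(0:2, cbind(0, c(0, 20, 40), 0))
  rec <- new_recording(rbind(c(1, 5), c(2, 5), c(10, 5)), 30000, g3)
  out <- common_median_reference(rec)
  expect_equal(out$traces[, 1], c(-1, 0, 8))
  expect_equal(out$traces[, 2], c(0, 0, 0))

  # identical channels -> all zeros
  v <- rnorm(100)
  rec2 <- new_recording(rbind(v, v, v), 30000, g3)
  expect_true(all(common_median_reference(rec2)$traces == 0))

  # per-sample median exactly 0 (odd channel count) + idempotence
  g7 <- probe_geometry(0:6, cbind(0, 20 * (0:6), 0))
  rec3 <- new_recording(matrix(rnorm(7 * 1000), 7), 30000, g7)
  out3 <- common_median_reference(rec3)
  expect_true(all(apply(out3$traces, 2, median) == 0))
  expect_equal(common_median_reference(out3)$traces, out3$traces)

  g1 <- probe_geometry(0L, cbind(0, 0, 0))
  expect_error(common_median_reference(
    new_recording(matrix(rnorm(10), 1), 30000, g1)), ">= 2 channels")
})

test_that("bandpass and CMR commute with channel permutation", {
  w <- tiny_world(seed = 2, n_units = 2, duration_s = 0.5, n_channels = 8)
  perm <- c(3, 1, 8, 5, 2, 7, 4, 6)
  permute <- function(rec) {
    g <- probe_geometry(rec$geometry$channel_ids[perm],
                        rec$geometry$positions[perm, ])
    new_recording(rec$traces[perm, ], rec$sampling_rate, g)
  }
  for (f in list(bandpass, common_median_reference)) {
    a <- f(permute(w$recording))$traces
    b <- permute(f(w$recording))$traces
    expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("anomalous-channel detection flags noise and power outliers", {
  # constructed fixture: a strong shared 700 Hz signal on most channels
  # (high neighbour coherence), two pure-noise channels, one 50 uV channel
  fs <- 30000
  n <- 30000
  shared <- 30 * sin(2 * pi * 700 * (0:(n - 1)) / fs)
  set.seed(42)
  traces <- t(vapply(1:12, function(i) shared + rnorm(n, sd = 5),
                     numeric(n)))
  traces[5, ] <- rnorm(n, sd = 5)      # decorrelated, normal power
  traces[9, ] <- rnorm(n, sd = 5)
  traces[12, ] <- rnorm(n, sd = 150)   # noise-contaminated (high power)
  g <- probe_geometry(0:11, cbind(0, 20 * (0:11), 0))
  rec <- new_recording(traces, fs, g)
  st <- detect_anomalous_channels(rec)
  expect_equal(st$label[5], "anomalous_coherence")
  expect_equal(st$label[9], "anomalous_coherence")
  expect_equal(st$label[12], "anomalous_power")
  expect_true(all(st$label[c(1:4, 6:8, 10:11)] == "good"))

  # invariant to a global gain
  st2 <- detect_anomalous_channels(
    new_recording(traces * 7.3, fs, g))
  expect_identical(st$label, st2$label)

  # declared dead channels are labelled and excluded from the statistics
  st3 <- detect_anomalous_channels(rec, declared_dead = c(0L, 3L))
  expect_true(all(st3$label[c(1, 4)] == "declared_dead"))
})

test_that("degraded channels are caught by the power test", {
  # background-noise-only recording: the clean power distribution is
  # tight, so the 50 uV replacements are unambiguous outliers
  g <- make_probe(32)
  rec <- render_recording(list(), g, duration_s = 1.5, noise_std = 10,
                          seed = 3)
  d <- degrade(rec, 10 / 32, seed = 13)           # 10 of 32 channels
  pp <- common_median_reference(bandpass(d$recording))
  st <- detect_anomalous_channels(pp, coherence_threshold = NA,
                                  declared_dead = integer(0))
  flagged <- st$channel_id[st$label == "anomalous_power"]
  expect_gte(length(intersect(flagged, d$plan$dead_channels)), 9)
  # the robust-z threshold of 4 admits the occasional false positive
  expect_lte(length(setdiff(flagged, d$plan$dead_channels)), 1)
})

test_that("two identical channels are both good", {
  v <- 20 * sin(2 * pi * 500 * (0:29999) / 30000)
  g <- probe_geometry(0:1, cbind(0, c(0, 20), 0))
  st <- detect_anomalous_channels(new_recording(rbind(v, v), 30000, g))
  expect_true(all(st$label == "good"))
})

test_that("channel status writes the documented CSV", {
  w <- tiny_world(seed = 1, n_units = 2, duration_s = 1)
  st <- detect_anomalous_channels(w$recording, coherence_threshold = NA)
  f <- withr::local_tempfile(fileext = ".csv")
  write_channel_status(st, f)
  back <- read.csv(f)
  expect_identical(names(back), c("channel_id", "label"))
  expect_equal(nrow(back), 32)
})
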