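test_that("ground-truth sampling is deterministic and respects contracts", {
  g <- make_probe(96)
  u1 <- sample_ground_truth(g, 10, duration_s = 30, seed = 7)
  u2 <- sample_ground_truth(g, 10, duration_s = 30, seed = 7)
  expect_identical(u1, u2)

  for (u in u1) {
    expect_gte(u$position[3], 0)                     # tissue side
    expect_true(all(diff(u$spike_times) > 0))        # strictly increasing
    expect_true(all(diff(u$spike_times) >= 2e-3))    # refractory thinning
    expect_true(all(u$spike_times <= 30))
  }

  u0 <- sample_ground_truth(g, 3, duration_s = 0, seed = 1)
  expect_true(all(vapply(u0, function(u) length(u$spike_times), 0L) == 0))

  expect_error(sample_ground_truth(g, 2, bounds = list(x = c(1, -1),
                                                       y = c(0, 1),
                                                       z = c(10, 20))),
               "empty or invalid bounds")
})

test_that("spike counts match the thinned-Poisson expectation", {
  g <- make_probe(96)
  units <- sample_ground_truth(g, 50, rate_hz = 5, duration_s = 90,
                               seed = 7)
  counts <- vapply(units, function(u) length(u$spike_times), 0)
  # Poisson(450) thinned by a 2 ms refractory period (~1% loss);
  # the mean over 50 units concentrates within a few sd/sqrt(50)
  expect_gt(mean(counts), 450 * 0.95)
  expect_lt(mean(counts), 450 * 1.02)
})

test_that("forward model follows the monopole 1/d decay exactly", {
  # one unit, no noise, channels at 20 and 40 um -> clean ptp ratio 2:1
  g <- probe_geometry(0:1, rbind(c(0, 20, 0), c(0, 40, 0)))
  u <- sample_ground_truth(g, 1, bounds = list(x = c(0, 0), y = c(0, 0),
                                               z = c(0, 0) + 1e-9),
                           duration_s = 1, min_peak_uv = 0, seed = 3)
  u[[1]]$position <- c(0, 0, 0)   # exactly 20 / 40 um from the channels
  rec <- render_recording(u, g, noise_std = 0, amp_modulation_cv = 0,
                          seed = 1)
  tpl <- attr(rec, "clean_templates")[[1]]
  ptp <- ptp_vector(tpl)
  expect_equal(unname(ptp[1] / ptp[2]), 2, tolerance = 1e-12)

  # full ptp vector equals base_amplitude * d_ref / d on a larger probe
  g2 <- column_probe(12)
  u2 <- sample_ground_truth(g2, 1, duration_s = 1, seed = 5)
  rec2 <- render_recording(u2, g2, noise_std = 0, amp_modulation_cv = 0,
                           seed = 2)
  ptp2 <- ptp_vector(attr(rec2, "clean_templates")[[1]])
  d <- sqrt(colSums((t(g2$positions) - u2[[1]]$position)^2))
  expect_equal(unname(ptp2), unname(u2[[1]]$base_amplitude * 20 / d),
               tolerance = 1e-9)
})

test_that("a neuron exactly on an electrode is rejected", {
  g <- column_probe(4)
  u <- sample_ground_truth(g, 1, duration_s = 1, seed = 1)
  u[[1]]$position <- g$positions[2, ]
  expect_error(render_recording(u, g, seed = 1), "singular decay")
})

test_that("amplitude modulation off makes all spikes identical", {
  g <- column_probe(6)
  u <- sample_ground_truth(g, 1, rate_hz = 20, duration_s = 2, seed = 2)
  rec <- render_recording(u, g, noise_std = 0, amp_modulation_cv = 0,
                          seed = 3)
  ws <- extract_snippets(rec, u[[1]]$spike_times, unit_id = 1)
  n <- dim(ws$snippets)[1]
  expect_gt(n, 5)
  # columns 2:60 are free of bleed-through from neighbouring spikes
  # (the refractory period keeps adjacent troughs >= 60 samples away)
  for (i in 2:n)
    expect_equal(ws$snippets[i, , 2:60], ws$snippets[1, , 2:60],
                 tolerance = 1e-12)
})

test_that("noise-only rendering is calibrated and Gaussian", {
  g <- probe_geometry(0:3, cbind(0, c(0, 20, 40, 60), 0))
  rec <- render_recording(list(), g, duration_s = 1e5 / 30000,
                          noise_std = 10, seed = 11)
  sds <- apply(rec$traces, 1, sd)
  expect_true(all(abs(sds / 10 - 1) < 0.02))
  skew <- apply(rec$traces, 1, function(x)
    mean((x - mean(x))^3) / sd(x)^3)
  expect_true(all(abs(skew) < 0.1))
})

test_that("degradation kills the requested channels and nothing else", {
  w <- tiny_world()
  d0 <- degrade(w$recording, 0, seed = 5)
  expect_identical(d0$recording$traces, w$recording$traces)
  expect_identical(d0$recording$dead_mask, w$recording$dead_mask)

  d5 <- degrade(w$recording, 0.5, seed = 5)
  expect_equal(length(d5$plan$dead_channels), 16)     # round(0.5 * 32)
  alive <- !d5$recording$dead_mask
  expect_identical(d5$recording$traces[alive, ],
                   w$recording$traces[alive, ])
  dead_idx <- which(d5$recording$dead_mask)
  expect_true(all(abs(apply(d5$recording$traces[dead_idx, ], 1, sd) /
                        50 - 1) < 0.05))
  # original untouched
  expect_true(all(!w$recording$dead_mask))

  expect_error(degrade(w$recording, 1.2, seed = 1), "fraction")
  expect_error(degrade(d5$recording, 0.6, seed = 1), "cumulative")
})

test_that("degradation masks are nested across levels under one seed", {
  w <- tiny_world()
  prev <- integer(0)
  for (f in c(0.1, 0.3, 0.5, 0.8, 0.94)) {
    d <- degrade(w$recording, f, seed = 9)
    expect_true(all(prev %in% d$plan$dead_channels))
    prev <- d$plan$dead_channels
  }
  # full-scale count: round(0.94 * 384) = 361
  expect_equal(round(0.94 * 384), 361)
})

test_that("rendering is a pure function of inputs and seed", {
  w1 <- tiny_world(seed = 4)
  w2 <- tiny_world(seed = 4)
  expect_identical(w1$recording$traces, w2$recording$traces)
})

test_that("ground truth JSON round-trips", {
  g <- column_probe(8)
  units <- sample_ground_truth(g, 3, duration_s = 2, seed = 6)
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(units, f)
  back <- read_ground_truth(f)
  expect_equal(length(back), 3)
  expect_equal(attr(back, "duration_s"), 2)
  for (i in 1:3) {
    expect_equal(back[[i]]$position, units[[i]]$position)
    expect_equal(back[[i]]$spike_times, units[[i]]$spike_times)
    expect_equal(back[[i]]$base_amplitude, units[[i]]$base_amplitude)
  }
})
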