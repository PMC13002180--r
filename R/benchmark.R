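#' Benchmark metrics
#'
#' Accuracy (fraction of estimates within a radius of the truth),
#' localization error (Euclidean distance estimate-to-truth) and
#' estimated drift (distance between a template's estimates with and
#' without degradation — a stability metric, not an accuracy metric).
#'
#' @name metrics
NULL

as_position_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- do.call(rbind, lapply(x, function(e)
      if (inherits(e, "slx_estimate")) e$position else e))
  x <- as.matrix(x)
  if (ncol(x) == 2L) x <- cbind(x, 0)
  if (ncol(x) != 3L) stop("positions must be (x, y, z)", call. = FALSE)
  x
}

#' Localization accuracy within a radius
#'
#' Fraction of paired estimate/truth positions whose Euclidean distance is
#' at most `radius_um` (inclusive boundary). The conventional radii are
#' 30 um for simulated ground truth and 50 um for experimental ground
#' truth, whose true positions are only known to electrode resolution.
#'
#' @param estimates,truths n x 3 position matrices (or lists of
#'   `slx_estimate` / position vectors), paired by row.
#' @param radius_um tolerance radius, um.
#' @return fraction in \[0, 1\].
#' @export
accuracy <- function(estimates, truths, radius_um = 30) {
  d <- localization_error(estimates, truths)$distances
  mean(d <= radius_um)
}

#' Localization error
#'
#' @inheritParams accuracy
#' @return list with `distances` (per-pair Euclidean distances, um) and
#'   `median`.
#' @export
localization_error <- function(estimates, truths) {
  e <- as_position_matrix(estimates)
  t <- as_position_matrix(truths)
  if (nrow(e) == 0L || nrow(t) == 0L)
    stop("empty position list", call. = FALSE)
  if (nrow(e) != nrow(t))
    stop("estimates and truths must be paired (equal length)",
         call. = FALSE)
  d <- sqrt(rowSums((e - t)^2))
  list(distances = d, median = median(d))
}

#' Estimated drift of template locations under degradation
#'
#' Per-unit Euclidean distance between the template location estimated on
#' a degraded recording and on the same recording without degradation.
#' Zero degradation gives zero drift by construction.
#'
#' @param degraded,clean data.frames with columns `unit_id`, `x`, `y`,
#'   `z` (or n x 3 matrices paired by row).
#' @return named numeric vector of per-unit drifts, um.
#' @export
estimated_drift <- function(degraded, clean) {
  if (is.data.frame(degraded) && is.data.frame(clean)) {
    if (!setequal(degraded$unit_id, clean$unit_id))
      stop("unit mismatch between degraded and clean estimates",
           call. = FALSE)
    clean <- clean[match(degraded$unit_id, clean$unit_id), ]
    d <- sqrt((degraded$x - clean$x)^2 + (degraded$y - clean$y)^2 +
                (degraded$z - clean$z)^2)
    names(d) <- degraded$unit_id
    return(d)
  }
  e <- as_position_matrix(degraded)
  c_ <- as_position_matrix(clean)
  if (nrow(e) != nrow(c_)) stop("unit mismatch", call. = FALSE)
  sqrt(rowSums((e - c_)^2))
}

# ---- pipeline internals ----------------------------------------------------

# Preprocess one (possibly degraded) recording and extract, per unit,
# the aligned snippets' template with its ptp and matched-filter
# amplitude vectors (the latter feed grid convolution when
# localize$gc$feature == "projection"), plus per-spike feature matrices.
# Channels flagged by detection are excluded only when
# preprocess$exclude_flagged is set; channels declared dead from the
# degradation plan are excluded when preprocess$declare_dead is set.
prepare_level <- function(recording, units, cfg, plan = NULL) {
  pp <- cfg$preprocess
  rec <- bandpass(recording, pp$low_hz, pp$high_hz, pp$order)
  rec <- common_median_reference(rec)
  declared <- if (isTRUE(pp$declare_dead) && !is.null(plan))
    plan$dead_channels else integer(0)
  status <- detect_anomalous_channels(
    rec,
    coherence_threshold = pp$coherence_threshold,
    k_neighbors = pp$k_neighbors,
    psd_band = pp$psd_band,
    psd_z_threshold = pp$psd_z_threshold,
    two_sided = isTRUE(pp$two_sided),
    declared_dead = declared)
  absent <- declared
  if (isTRUE(pp$exclude_flagged))
    absent <- union(absent, status$channel_id[status$label != "good"])
  wf <- cfg$waveforms
  gc_proj <- identical(cfg$localize$gc$feature %||% "projection",
                       "projection")
  per_unit <- lapply(units, function(u) {
    ws <- extract_snippets(rec, u$spike_times, wf$pre_ms, wf$post_ms,
                           unit_id = u$unit_id)
    if (dim(ws$snippets)[1] == 0L)
      return(list(unit_id = u$unit_id, template_ptp = NULL,
                  gc_template = NULL, spike_ptp = NULL,
                  gc_spike = NULL))
    ws <- align_to_trough(ws, wf$max_jitter_ms)
    tpl <- compute_template(ws)
    nsp <- dim(ws$snippets)[1]
    spk <- t(apply(ws$snippets, 1, function(m)
      matrixStats::rowMaxs(m) - matrixStats::rowMins(m)))
    colnames(spk) <- as.character(ws$channel_ids)
    if (gc_proj) {
      ref <- tpl$waveform[channel_index_of(tpl), ]
      gc_tpl <- matched_amplitudes(tpl, ref)
      gc_spk <- t(apply(ws$snippets, 1, function(m)
        matched_amplitudes(`rownames<-`(m, rownames(tpl$waveform)),
                           ref)))
      colnames(gc_spk) <- as.character(ws$channel_ids)
    } else {
      gc_tpl <- tpl$ptp
      gc_spk <- spk
    }
    abs_chr <- as.character(absent)
    spk[, abs_chr] <- NA_real_
    gc_spk[, abs_chr] <- NA_real_
    list(unit_id = u$unit_id,
         template_ptp = ptp_vector(tpl, exclude = absent),
         gc_template = gc_tpl[!(names(gc_tpl) %in% abs_chr)],
         spike_ptp = spk,
         gc_spike = gc_spk)
  })
  list(per_unit = per_unit, status = status, absent = absent)
}

# row index of a template's peak channel inside its own waveform matrix
channel_index_of <- function(tpl) {
  match(as.character(tpl$peak_channel), rownames(tpl$waveform))
}

localizer_call <- function(algorithm, ptp, geometry, loc_cfg, grid) {
  switch(algorithm,
         COM = localize_com(ptp, geometry,
                            radius_um = loc_cfg$com$radius_um),
         MT = localize_mt(ptp, geometry,
                          radius_um = loc_cfg$mt$radius_um,
                          max_distance_um = loc_cfg$mt$max_distance_um),
         GC = localize_gc(ptp, geometry, grid = grid,
                          radius_um = loc_cfg$gc$radius_um,
                          percentile_top = loc_cfg$gc$percentile_top),
         stop("unknown algorithm ", algorithm, call. = FALSE))
}

make_gc_grid <- function(geometry, loc_cfg) {
  build_grid(geometry,
             radius_um = loc_cfg$gc$radius_um,
             resolution_um = loc_cfg$gc$resolution_um,
             z_max_um = loc_cfg$gc$z_max_um,
             sigma_um = loc_cfg$gc$sigma_um)
}

#' Run the electrode-degradation benchmark sweep
#'
#' For every (seed, degradation level, algorithm): simulate a ground-truth
#' recording, degrade it, run the preprocessing chain, extract templates
#' (and optionally per-spike footprints) at the ground-truth spike times,
#' localize, and score accuracy, localization error and drift relative to
#' the same seed's 0% level. One seed is one trial: the unit arrangement,
#' the recording noise and the degradation pattern all derive from it,
#' and the degradation pattern is *nested* across levels (a channel dead
#' at level k stays dead at every higher level), so drift reflects signal
#' loss rather than channel reshuffling. The full sweep is deterministic
#' given the config.
#'
#' @param config a config list from [slx_config()] / [desk_config()].
#' @param out_dir optional directory; when given, tidy CSVs
#'   (`records.csv`, `per_unit.csv`) and a JSON summary are written.
#' @return data.frame of benchmark records, one row per (seed, level,
#'   algorithm, target): `seed`, `degradation_fraction`, `algorithm`,
#'   `target`, `accuracy`, `median_error_um`, `drift_um` (median per-unit
#'   drift; templates only), `runtime_s`, `n`, `n_failed`,
#'   `error_distribution` (semicolon-joined um). The per-unit long table
#'   is attached as attribute `"per_unit"`, and the total failure count
#'   as `"n_failed_total"`.
#' @export
run_degradation_sweep <- function(config = desk_config(),
                                  out_dir = NULL) {
  cfg <- validate_config(config)
  bm <- cfg$benchmark
  geometry <- do.call(make_probe, cfg$probe)
  grid <- if ("GC" %in% bm$algorithms)
    make_gc_grid(geometry, cfg$localize)
  records <- list()
  per_unit <- list()
  n_failed_total <- 0L

  for (seed in bm$seeds) {
    sm <- cfg$simulate
    units <- sample_ground_truth(
      geometry, sm$n_neurons,
      rate_hz = sm$rate_hz, duration_s = sm$duration_s,
      refractory_ms = sm$refractory_ms, seed = child_seed(seed, 10))
    truths <- do.call(rbind, lapply(units, `[[`, "position"))
    clean_rec <- render_recording(
      units, geometry, noise_std = sm$noise_std,
      sampling_rate = sm$sampling_rate,
      amp_modulation_cv = sm$amp_modulation_cv, d_ref = sm$d_ref,
      decay_power = sm$decay_power, seed = child_seed(seed, 20))
    attr(clean_rec, "clean_templates") <- NULL
    baseline <- list()  # level-0 template estimates per algorithm

    for (level in bm$levels) {
      if (level > 0) {
        dg <- degrade(clean_rec, level, noise_std = cfg$degrade$noise_std,
                      seed = child_seed(seed, 30))
        rec <- dg$recording; plan <- dg$plan
      } else {
        rec <- clean_rec; plan <- NULL
      }
      prep <- prepare_level(rec, units, cfg, plan)
      rm(rec)

      for (alg in bm$algorithms) {
        for (target in bm$targets) {
          t0 <- proc.time()[["elapsed"]]
          est <- data.frame()
          fails <- 0L
          for (pu in prep$per_unit) {
            if (target == "template") {
              if (is.null(pu$template_ptp)) { fails <- fails + 1L; next }
              feat <- if (alg == "GC") pu$gc_template
                      else pu$template_ptp
              e <- tryCatch(
                localizer_call(alg, feat, geometry, cfg$localize, grid),
                error = function(e) e)
              if (inherits(e, "error")) { fails <- fails + 1L; next }
              est <- rbind(est, data.frame(
                unit_id = pu$unit_id, x = e$position[1],
                y = e$position[2], z = e$position[3]))
            } else {
              if (is.null(pu$spike_ptp)) { fails <- fails + 1L; next }
              spk <- if (alg == "GC") pu$gc_spike else pu$spike_ptp
              if (nrow(spk) > bm$max_spikes_per_unit)
                spk <- spk[seq_len(bm$max_spikes_per_unit), ,
                           drop = FALSE]
              res <- if (alg == "COM")
                localize_many(spk, geometry, alg,
                              radius_um = cfg$localize$com$radius_um)
              else if (alg == "MT")
                localize_many(spk, geometry, alg,
                              radius_um = cfg$localize$mt$radius_um,
                              max_distance_um =
                                cfg$localize$mt$max_distance_um)
              else
                localize_many(spk, geometry, alg, grid = grid,
                              radius_um = cfg$localize$gc$radius_um,
                              percentile_top =
                                cfg$localize$gc$percentile_top)
              fails <- fails + sum(!res$ok)
              res <- res[res$ok, , drop = FALSE]
              if (nrow(res))
                est <- rbind(est, data.frame(unit_id = pu$unit_id,
                                             x = res$x, y = res$y,
                                             z = res$z))
            }
          }
          runtime <- proc.time()[["elapsed"]] - t0
          n_failed_total <- n_failed_total + fails

          if (nrow(est) == 0L) {
            records[[length(records) + 1L]] <- data.frame(
              seed = seed, degradation_fraction = level,
              algorithm = alg, target = target, accuracy = NA_real_,
              median_error_um = NA_real_, drift_um = NA_real_,
              runtime_s = runtime, n = 0L, n_failed = fails,
              failed = TRUE, error_distribution = "")
            next
          }
          tru <- truths[est$unit_id, , drop = FALSE]
          le <- localization_error(as.matrix(est[, c("x", "y", "z")]),
                                   tru)
          drift <- NA_real_
          if (target == "template") {
            key <- alg
            if (level == min(bm$levels) && min(bm$levels) == 0)
              baseline[[key]] <- est
            if (!is.null(baseline[[key]])) {
              common <- intersect(est$unit_id, baseline[[key]]$unit_id)
              dr <- estimated_drift(
                est[match(common, est$unit_id), ],
                baseline[[key]][match(common, baseline[[key]]$unit_id), ])
              drift <- if (length(dr)) median(dr) else NA_real_
              per_unit[[length(per_unit) + 1L]] <- data.frame(
                seed = seed, degradation_fraction = level,
                algorithm = alg, target = target,
                unit_id = est$unit_id, error_um = le$distances,
                drift_um = dr[match(est$unit_id, common)])
            }
          } else {
            per_unit[[length(per_unit) + 1L]] <- data.frame(
              seed = seed, degradation_fraction = level,
              algorithm = alg, target = target, unit_id = est$unit_id,
              error_um = le$distances, drift_um = NA_real_)
          }
          records[[length(records) + 1L]] <- data.frame(
            seed = seed, degradation_fraction = level, algorithm = alg,
            target = target,
            accuracy = accuracy(as.matrix(est[, c("x", "y", "z")]), tru,
                                bm$accuracy_radius_um),
            median_error_um = le$median, drift_um = drift,
            runtime_s = runtime, n = nrow(est), n_failed = fails,
            failed = FALSE,
            error_distribution = paste(signif(le$distances, 6),
                                       collapse = ";"))
        }
      }
      rm(prep); gc(FALSE)
    }
    rm(clean_rec); gc(FALSE)
  }

  records <- do.call(rbind, records)
  per_unit <- if (length(per_unit)) do.call(rbind, per_unit)
              else data.frame()
  attr(records, "per_unit") <- per_unit
  attr(records, "n_failed_total") <- n_failed_total
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(records, file.path(out_dir, "records.csv"),
              row.names = FALSE)
    write.csv(per_unit, file.path(out_dir, "per_unit.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      list(n_records = nrow(records), n_failed_total = n_failed_total,
           levels = bm$levels, seeds = bm$seeds,
           algorithms = bm$algorithms),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE)
  }
  records
}

#' Parameter grid search over localization regularization
#'
#' Re-localizes the same degraded datasets under a grid of regularization
#' parameters — for MT the channel-selection radius crossed with the
#' candidate-window size, for GC the channel-selection radius crossed
#' with the top-convolution percentile (COM is reported at its defaults
#' only) — and reports the median spike localization error per cell and
#' level, plus each cell's error change between the lowest and highest
#' degradation level.
#'
#' @param config a config list; the `gridsearch` section holds the
#'   parameter grids, levels and seed.
#' @return data.frame with columns `algorithm`, `param1`, `value1`,
#'   `param2`, `value2`, `level`, `median_error_um`, `n`; the per-cell
#'   lowest-to-highest-level delta table is attached as attribute
#'   `"delta"`.
#' @export
parameter_grid_search <- function(config = desk_config()) {
  cfg <- validate_config(config)
  gs <- cfg$gridsearch
  geometry <- do.call(make_probe, cfg$probe)
  sm <- cfg$simulate
  seed <- gs$seed
  units <- sample_ground_truth(
    geometry, sm$n_neurons, rate_hz = sm$rate_hz,
    duration_s = sm$duration_s, refractory_ms = sm$refractory_ms,
    seed = child_seed(seed, 10))
  truths <- do.call(rbind, lapply(units, `[[`, "position"))
  clean_rec <- render_recording(
    units, geometry, noise_std = sm$noise_std,
    sampling_rate = sm$sampling_rate,
    amp_modulation_cv = sm$amp_modulation_cv, d_ref = sm$d_ref,
    decay_power = sm$decay_power, seed = child_seed(seed, 20))
  attr(clean_rec, "clean_templates") <- NULL

  cells <- list()
  add_cell <- function(alg, p1, v1, p2, v2)
    cells[[length(cells) + 1L]] <<- list(alg = alg, p1 = p1, v1 = v1,
                                         p2 = p2, v2 = v2)
  for (r in gs$mt$radius_um)
    for (m in gs$mt$max_distance_um)
      add_cell("MT", "radius_um", r, "max_distance_um", m)
  for (r in gs$gc$radius_um)
    for (p in gs$gc$percentile)
      add_cell("GC", "radius_um", r, "percentile", p)
  add_cell("COM", "radius_um", cfg$localize$com$radius_um, "none", NA)

  rows <- list()
  for (level in gs$levels) {
    if (level > 0) {
      dg <- degrade(clean_rec, level, noise_std = cfg$degrade$noise_std,
                    seed = child_seed(seed, 30))
      rec <- dg$recording; plan <- dg$plan
    } else {
      rec <- clean_rec; plan <- NULL
    }
    prep <- prepare_level(rec, units, cfg, plan)
    rm(rec)
    # spike footprints pooled over units, truth repeated per spike
    spk <- list(); gspk <- list(); tru <- list()
    for (pu in prep$per_unit) {
      if (is.null(pu$spike_ptp)) next
      keep <- seq_len(min(nrow(pu$spike_ptp), gs$max_spikes_per_unit))
      spk[[length(spk) + 1L]] <- pu$spike_ptp[keep, , drop = FALSE]
      gspk[[length(gspk) + 1L]] <- pu$gc_spike[keep, , drop = FALSE]
      tru[[length(tru) + 1L]] <-
        matrix(truths[pu$unit_id, ], length(keep), 3, byrow = TRUE)
    }
    spk <- do.call(rbind, spk)
    gspk <- do.call(rbind, gspk)
    tru <- do.call(rbind, tru)

    for (cell in cells) {
      res <- switch(cell$alg,
        COM = localize_many(spk, geometry, "COM", radius_um = cell$v1),
        MT = localize_many(spk, geometry, "MT", radius_um = cell$v1,
                           max_distance_um = cell$v2),
        GC = {
          g <- build_grid(geometry, radius_um = cell$v1,
                          resolution_um = cfg$localize$gc$resolution_um,
                          z_max_um = cfg$localize$gc$z_max_um,
                          sigma_um = cfg$localize$gc$sigma_um)
          localize_many(gspk, geometry, "GC", grid = g,
                        radius_um = cell$v1, percentile_top = cell$v2)
        })
      ok <- res$ok
      med <- if (any(ok))
        localization_error(as.matrix(res[ok, c("x", "y", "z")]),
                           tru[ok, , drop = FALSE])$median
      else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = cell$alg, param1 = cell$p1, value1 = cell$v1,
        param2 = cell$p2, value2 = cell$v2, level = level,
        median_error_um = med, n = sum(ok))
    }
    rm(prep); gc(FALSE)
  }
  out <- do.call(rbind, rows)
  lo <- min(gs$levels); hi <- max(gs$levels)
  key <- c("algorithm", "param1", "value1", "param2", "value2")
  a <- out[out$level == lo, ]; b <- out[out$level == hi, ]
  i <- match(interaction(a[key]), interaction(b[key]))
  delta <- cbind(a[key],
                 delta_error_um = b$median_error_um[i] -
                   a$median_error_um)
  attr(out, "delta") <- delta
  out
}
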