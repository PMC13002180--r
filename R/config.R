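#' Run configuration
#'
#' A single nested list drives the whole pipeline; every default matches
#' the conventional value where one exists (10 uV simulation noise, 50 uV
#' degradation noise, 30 kHz, 300-3,000 Hz order-5 causal bandpass, 75 um
#' MT radius, 1,000 um MT candidate window, 40 um GC radius, 5 um grid
#' resolution, top 5% of convolutions, 30 um simulated-mode accuracy
#' radius). [slx_config()] is the full-scale preset (50 neurons,
#' 90 s, 384 channels, 25 degradation levels from 0 to 94%, five seeds);
#' [desk_config()] is the scaled-down preset that drives the test suite
#' (10 neurons, 30 s, 96 channels).
#'
#' @param ... named overrides merged into the preset, e.g.
#'   `desk_config(benchmark = list(seeds = 0:2))`. Unknown keys are
#'   rejected.
#' @return a validated config list.
#' @export
slx_config <- function(...) {
  base <- list(
    probe = list(n_channels = 384L, layout = "staggered",
                 x_pitch_um = 32, y_pitch_um = 20, z_um = 0,
                 name = NULL),
    simulate = list(n_neurons = 50L, duration_s = 90, rate_hz = 5,
                    refractory_ms = 2, noise_std = 10,
                    amp_modulation_cv = 0.05, d_ref = 20,
                    decay_power = 1, sampling_rate = 30000),
    degrade = list(noise_std = 50),
    preprocess = list(low_hz = 300, high_hz = 3000, order = 5L,
                      coherence_threshold = NA, k_neighbors = 4L,
                      psd_band = c(300, 3000), psd_z_threshold = 4,
                      two_sided = FALSE, declare_dead = FALSE,
                      exclude_flagged = FALSE),
    waveforms = list(pre_ms = 1, post_ms = 2, max_jitter_ms = 0.5),
    localize = list(
      com = list(radius_um = 75),
      mt = list(radius_um = 75, max_distance_um = 1000),
      gc = list(radius_um = 40, resolution_um = 5, z_max_um = 100,
                sigma_um = 40, percentile_top = 5,
                feature = "projection")),
    benchmark = list(levels = seq(0, 0.94, length.out = 25),
                     seeds = 0:4,
                     algorithms = c("COM", "MT", "GC"),
                     targets = "template",
                     accuracy_radius_um = 30,
                     max_spikes_per_unit = Inf),
    gridsearch = list(
      mt = list(radius_um = c(25, 75, 225),
                max_distance_um = c(100, 1000, 10000)),
      gc = list(radius_um = c(13, 40, 120),
                percentile = c(1.7, 5, 15)),
      levels = c(0, 0.94), seed = 0L, max_spikes_per_unit = 25L),
    seed = 0L,
    out_dir = NULL)
  validate_config(merge_config(base, list(...)))
}

#' @rdname slx_config
#' @export
desk_config <- function(...) {
  slx_config(
    probe = list(n_channels = 96L),
    simulate = list(n_neurons = 10L, duration_s = 30),
    benchmark = list(levels = seq(0, 0.9, by = 0.1), seeds = 0:2),
    gridsearch = list(levels = c(0, 0.9)),
    ...)
}

# Recursive merge of overrides into defaults; unknown keys are an error.
merge_config <- function(base, override, path = "") {
  if (length(override) == 0L) return(base)
  nm <- names(override)
  if (is.null(nm) || any(nm == ""))
    stop("config overrides must be named (at ", path, ")", call. = FALSE)
  for (i in seq_along(override)) {   # by index: names may repeat
    k <- nm[i]
    full <- paste0(path, k)
    if (!k %in% names(base))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[i]]))
      base[[k]] <- merge_config(base[[k]], override[[i]],
                                paste0(full, "$"))
    else
      base[k] <- override[i]   # [k] <- keeps explicit NULLs
  }
  base
}

#' Validate a configuration list
#'
#' Checks structure and value sanity (levels within \[0, 1\] and sorted
#' ascending, algorithms known, positive rates). Called internally by the
#' sweep entry points; exposed for CLI use.
#'
#' @param config a config list.
#' @return the (normalised) config, invisibly usable.
#' @export
validate_config <- function(config) {
  need <- c("probe", "simulate", "degrade", "preprocess", "waveforms",
            "localize", "benchmark", "gridsearch", "seed", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(names(config), need)
  if (length(extra))
    stop("unknown config key: ", extra[1], call. = FALSE)
  bm <- config$benchmark
  if (any(bm$levels < 0 | bm$levels > 1))
    stop("benchmark$levels must be within [0, 1]", call. = FALSE)
  config$benchmark$levels <- sort(bm$levels)
  bad <- setdiff(bm$algorithms, c("COM", "MT", "GC"))
  if (length(bad))
    stop("unknown algorithm in config: ", bad[1], call. = FALSE)
  if (!all(bm$targets %in% c("template", "spike")))
    stop("benchmark$targets must be 'template' and/or 'spike'",
         call. = FALSE)
  if (config$simulate$rate_hz <= 0 || config$simulate$duration_s < 0)
    stop("simulate$rate_hz must be > 0 and duration_s >= 0",
         call. = FALSE)
  config
}

#' Read / write a config as JSON
#'
#' @param path JSON file path.
#' @param config a config list.
#' @return `read_config()` returns a validated config (file values are
#'   merged over the full-scale preset, so a config file may be partial).
#'   A malformed file raises an `slx_config_error` naming the offending
#'   key, which [cli()] maps to exit code 2.
#' @export
read_config <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_config("cannot read config ", path, ": ",
                                conditionMessage(e)))
  tryCatch(do.call(slx_config, obj),
           error = function(e) stop_config(conditionMessage(e)))
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
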