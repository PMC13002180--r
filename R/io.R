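#' Ground-truth unit readers / writers
#'
#' JSON layout: array of objects `{unit_id, position, base_amplitude,
#' spike_times, shape}` plus a top-level `duration_s`. Positions in um,
#' times in seconds.
#'
#' @param units list of `slx_unit` (from [sample_ground_truth()]).
#' @param path JSON file path.
#' @return `read_ground_truth()` returns the unit list with its
#'   `duration_s` attribute; `write_ground_truth()` returns `path`
#'   invisibly.
#' @export
write_ground_truth <- function(units, path) {
  jsonlite::write_json(list(
    duration_s = attr(units, "duration_s"),
    units = lapply(units, function(u)
      list(unit_id = u$unit_id, position = u$position,
           base_amplitude = u$base_amplitude,
           spike_times = u$spike_times, shape = u$shape))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  units <- lapply(seq_len(nrow(obj$units)), function(i) {
    row <- obj$units[i, ]
    structure(list(unit_id = row$unit_id,
                   position = unlist(row$position),
                   base_amplitude = row$base_amplitude,
                   spike_times = as.numeric(unlist(row$spike_times)),
                   shape = as.list(unlist(row$shape))),
              class = "slx_unit")
  })
  attr(units, "duration_s") <- obj$duration_s
  units
}
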