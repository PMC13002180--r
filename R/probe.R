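#' Probe geometries
#'
#' A probe geometry is a planar multi-electrode array: a set of channels with
#' (x, y, z) positions in micrometres, all sharing the same z (the probe
#' plane; z is orthogonal to the array, neurons live at z >= 0).
#'
#' @param channel_ids integer vector of unique channel ids.
#' @param positions numeric matrix (n x 3) of channel positions in um.
#' @param name free-text probe name.
#' @return an object of class `slx_probe`: a list with elements
#'   `channel_ids`, `positions` (n x 3 matrix with rownames = channel ids)
#'   and `name`.
#' @export
probe_geometry <- function(channel_ids, positions, name = "custom") {
  channel_ids <- as.integer(channel_ids)
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L)
    stop("`positions` must have three columns (x, y, z)", call. = FALSE)
  if (nrow(positions) != length(channel_ids))
    stop("positions / channel_ids length mismatch", call. = FALSE)
  if (anyDuplicated(channel_ids))
    stop("channel_ids must be unique", call. = FALSE)
  if (!all(is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  if (length(unique(positions[, 3])) != 1L)
    stop("planar array required: all channel z must be equal", call. = FALSE)
  storage.mode(positions) <- "double"
  dimnames(positions) <- list(as.character(channel_ids), c("x", "y", "z"))
  structure(list(channel_ids = channel_ids, positions = positions,
                 name = name),
            class = "slx_probe")
}

#' Build a Neuropixels-like planar probe
#'
#' The default plan is a staggered two-column layout: columns at x = 0 and
#' x = `x_pitch_um`, rows every `y_pitch_um`, with the second column offset
#' vertically by half a row. 384 channels span ~3.8 mm along y and well
#' under 60 um along x, matching the aspect ratio of a Neuropixels shank.
#'
#' @param n_channels number of channels (>= 4; monopolar triangulation needs
#'   at least 4 observations for its 4 unknowns).
#' @param layout `"staggered"` (two columns, default) or `"single_column"`.
#' @param x_pitch_um horizontal distance between the two columns (um).
#' @param y_pitch_um vertical distance between successive rows of one
#'   column (um).
#' @param z_um probe plane height (um); all channels share it.
#' @param name probe name.
#' @return an `slx_probe`.
#' @examples
#' p <- make_probe(384)
#' diff(range(p$positions[, "y"]))  # ~3830 um
#' @export
make_probe <- function(n_channels = 384L,
                       layout = c("staggered", "single_column"),
                       x_pitch_um = 32, y_pitch_um = 20, z_um = 0,
                       name = NULL) {
  layout <- match.arg(layout)
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 4L)
    stop("invalid geometry: n_channels must be >= 4 ",
         "(monopolar triangulation needs 4 observations)", call. = FALSE)
  i <- seq_len(n_channels) - 1L
  if (layout == "staggered") {
    col <- i %% 2L
    x <- col * x_pitch_um
    y <- (i %/% 2L) * y_pitch_um + col * (y_pitch_um / 2)
  } else {
    x <- rep(0, n_channels)
    y <- i * y_pitch_um
  }
  probe_geometry(i, cbind(x, y, rep(z_um, n_channels)),
                 name = name %||% sprintf("%s-%d", layout, n_channels))
}

#' @export
print.slx_probe <- function(x, ...) {
  ext <- apply(x$positions[, 1:2, drop = FALSE], 2, function(v) diff(range(v)))
  cat(sprintf("<slx_probe '%s'> %d channels, extent %.0f x %.0f um, z = %g\n",
              x$name, length(x$channel_ids), ext[1], ext[2],
              x$positions[1, 3]))
  invisible(x)
}

n_channels <- function(geometry) length(geometry$channel_ids)

# Row indices of `ids` inside the geometry (stops on unknown ids).
channel_index <- function(geometry, ids) {
  idx <- match(as.integer(ids), geometry$channel_ids)
  if (anyNA(idx)) stop("unknown channel id(s)", call. = FALSE)
  idx
}

#' Read / write probe geometries
#'
#' CSV dialect: columns `channel_id,x,y,z` (um). JSON dialect: object with
#' fields `name` and `channels` = array of `{channel_id, x, y, z}`. The two
#' dialects round-trip to identical geometries at full float precision.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @param geometry an `slx_probe`.
#' @return `read_geometry()` returns an `slx_probe`; `write_geometry()`
#'   returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(obj$channels)
    nm <- obj$name %||% "unnamed"
  } else {
    df <- read.csv(path)
    nm <- sub("\\.[^.]*$", "", basename(path))
  }
  need <- c("channel_id", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("geometry file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$channel_id)) {
    row <- which(duplicated(df$channel_id))[1]
    stop("duplicate channel_id at row ", row, " of ", path, call. = FALSE)
  }
  probe_geometry(df$channel_id, cbind(df$x, df$y, df$z), name = nm)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geometry, path) {
  df <- data.frame(channel_id = geometry$channel_ids,
                   x = geometry$positions[, 1],
                   y = geometry$positions[, 2],
                   z = geometry$positions[, 3])
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(name = geometry$name, channels = df), path,
                         auto_unbox = TRUE, digits = NA)
  } else {
    write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
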