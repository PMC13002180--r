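#' Spike source localization
#'
#' Three estimators of a neuron's position from the per-channel
#' peak-to-peak amplitude footprint `ptp` of a spike or template on a
#' planar probe:
#' \describe{
#'   \item{COM}{center of mass — the ptp-weighted average of electrode
#'     positions. Fast, but confined to the convex hull of the electrodes
#'     and to the probe plane (z = 0).}
#'   \item{MT}{monopolar triangulation — fits a point source with
#'     amplitude c and 1/distance decay, `V_j = c / ||p - p_j||`, by
#'     bounded nonlinear least squares over (x, y, z, c). Can localize
#'     off the array, at the price of an optimization per spike.}
#'   \item{GC}{grid convolution — scores a dense lattice of hypothetical
#'     source positions by the similarity between the observed footprint
#'     and a Gaussian-decay prototype footprint at each node, then
#'     averages the top-scoring nodes.}
#' }
#' All three consume the output of [select_channels()], which restricts
#' the footprint to a local radius around the peak channel (the
#' regularization the reference implementations apply by default).
#'
#' @name localize
NULL

new_estimate <- function(position, algorithm, aux = list()) {
  structure(list(position = c(x = position[[1]], y = position[[2]],
                              z = position[[3]]),
                 algorithm = algorithm, aux = aux),
            class = "slx_estimate")
}

#' @export
print.slx_estimate <- function(x, ...) {
  cat(sprintf("<slx_estimate %s> (%.2f, %.2f, %.2f) um\n", x$algorithm,
              x$position[1], x$position[2], x$position[3]))
  invisible(x)
}

#' Select contributing channels around the peak channel
#'
#' The peak channel is the present channel with the largest ptp (ties
#' broken toward the lowest channel id); the selection is every present
#' channel within `radius_um` (inclusive) of it.
#'
#' @param ptp named nonnegative vector of peak-to-peak amplitudes over the
#'   *present* channels (names = channel ids; absent channels simply
#'   missing, see [ptp_vector()]).
#' @param geometry an `slx_probe`.
#' @param radius_um selection radius in um (`Inf` = all present channels).
#' @return list with `channel_ids`, `positions` (n x 3), `ptp`,
#'   `peak_channel`.
#' @export
select_channels <- function(ptp, geometry, radius_um = Inf) {
  if (length(ptp) == 0L)
    stop("no present channels: no signal to localize", call. = FALSE)
  ids <- as.integer(names(ptp))
  if (anyNA(ids))
    stop("`ptp` must be named by channel ids", call. = FALSE)
  ord <- order(ids)               # lowest-id tie-break for the peak
  ids <- ids[ord]
  ptp <- ptp[ord]
  idx <- channel_index(geometry, ids)
  pos <- geometry$positions[idx, , drop = FALSE]
  peak <- which.max(ptp)
  keep <- dist_to_points(pos[peak, ], pos) <= radius_um
  list(channel_ids = ids[keep],
       positions = pos[keep, , drop = FALSE],
       ptp = unname(ptp[keep]),
       peak_channel = ids[peak])
}

#' Center-of-mass localization
#'
#' `p = sum_j ptp_j p_j / sum_j ptp_j` over the selected channels. The
#' estimate is a convex combination of electrode positions, so it always
#' lies inside their convex hull and on the probe plane.
#'
#' @inheritParams select_channels
#' @return an `slx_estimate` with `algorithm = "COM"`.
#' @export
localize_com <- function(ptp, geometry, radius_um = Inf) {
  sel <- select_channels(ptp, geometry, radius_um)
  s <- sum(sel$ptp)
  if (s <= 0)
    stop("degenerate signal: selected ptp sums to 0", call. = FALSE)
  w <- sel$ptp / s
  new_estimate(colSums(sel$positions * w), "COM")
}

#' Monopolar triangulation
#'
#' Minimizes `sum_j (ptp_j - c / ||p - p_j||)^2` over position p and
#' source constant c by bounded nonlinear least squares (analytic
#' gradient), initialized at the center-of-mass estimate with z = 20 um
#' and `c0 = ptp_peak * ||p0 - p_peak||`. The position is constrained to
#' an axis-wise box of half-width `max_distance_um` around the COM
#' initialization in x and y, and to `[0, max_distance_um]` above the
#' probe plane in z (a planar array cannot distinguish the sign of z).
#'
#' @inheritParams select_channels
#' @param radius_um channel-selection radius (default 75 um).
#' @param max_distance_um candidate-window half-width (default 1000 um).
#' @return an `slx_estimate` with `algorithm = "MT"`; `aux` carries the
#'   fitted source constant `c`, the final sum-of-squares `residual`, and
#'   a `converged` flag (a non-converged fit is returned at the best
#'   iterate with a warning).
#' @export
localize_mt <- function(ptp, geometry, radius_um = 75,
                        max_distance_um = 1000) {
  sel <- select_channels(ptp, geometry, radius_um)
  m <- length(sel$ptp)
  if (m < 4L)
    stop("underdetermined: monopolar triangulation needs >= 4 channels ",
         "(got ", m, ")", call. = FALSE)
  pos <- sel$positions
  obs <- sel$ptp
  z_plane <- pos[1, 3]
  w <- obs / sum(obs)
  com <- colSums(pos * w)
  p0 <- c(com[1], com[2], z_plane + 20)
  lower <- c(com[1] - max_distance_um, com[2] - max_distance_um, z_plane)
  upper <- c(com[1] + max_distance_um, com[2] + max_distance_um,
             z_plane + max_distance_um)
  # the source constant is linear-in-1/d, so profile it out: for fixed p
  # the least-squares optimum is c*(p) = sum(ptp/d) / sum(1/d^2), leaving
  # a well-conditioned 3-parameter problem with the same minimizer.
  c_star <- function(d) sum(obs / d) / sum(1 / d^2)
  fn <- function(th) {
    d <- pmax(dist_to_points(th, pos), 1e-9)
    cc <- c_star(d)
    sum((obs - cc / d)^2)
  }
  gr <- function(th) {
    d <- pmax(dist_to_points(th, pos), 1e-9)
    cc <- c_star(d)
    r <- obs - cc / d
    dp <- sweep(-pos, 2, th, "+")          # rows p - p_j
    colSums(2 * r * cc * dp / d^3)         # envelope: dc*/dp term vanishes
  }
  # multi-start in z: the loss has spurious minima when the start is far
  # from the source on the scale of the array, so try the conventional
  # 20 um plus starts scaled to the local channel spacing.
  spread <- median(dist_to_points(pos[which.max(obs), ], pos))
  z_starts <- unique(pmin(pmax(c(20, 0.5 * spread, 2 * spread),
                               1e-3), max_distance_um))
  fit <- NULL
  for (z0 in z_starts) {
    f <- nlminb(c(p0[1], p0[2], z_plane + z0), fn, gradient = gr,
                lower = lower, upper = upper,
                control = list(iter.max = 500L, eval.max = 1000L,
                               rel.tol = 1e-14, x.tol = 1e-12))
    if (is.null(fit) || f$objective < fit$objective) fit <- f
  }
  converged <- fit$convergence == 0 ||
    grepl("relative convergence|both X|singular convergence",
          fit$message %||% "")
  if (!converged)
    warning("monopolar triangulation did not converge (",
            fit$message, "); returning best iterate")
  d_fit <- pmax(dist_to_points(fit$par, pos), 1e-9)
  new_estimate(fit$par, "MT",
               aux = list(c = c_star(d_fit), residual = fit$objective,
                          converged = converged))
}

#' Build a dense candidate grid for grid convolution
#'
#' Regular lattice at `resolution_um` spacing covering the probe's x-y
#' extent padded by `radius_um` on each side, replicated at z levels
#' `0, resolution, ... , z_max_um` above the probe plane (the grid is
#' denser than the electrodes; 5 um by default).
#'
#' @param geometry an `slx_probe`.
#' @param radius_um padding around the probe extent (and the default
#'   node-selection radius, see [localize_gc()]).
#' @param resolution_um lattice spacing, um.
#' @param z_max_um highest z level above the probe plane.
#' @param sigma_um decay scale(s) of the prototype footprints, um; when
#'   several are given the best-scoring scale is used per node.
#' @param kernel prototype decay law in 3-D source-to-channel distance d:
#'   `"exponential"` (`exp(-d / sigma)`, default) or `"gaussian"`
#'   (`exp(-d^2 / (2 sigma^2))`). On a planar array the Gaussian
#'   factorizes into an xy part times a common z factor, which the
#'   per-node normalization cancels, leaving the similarity exactly blind
#'   to depth — so the exponential form (which does not factorize, and
#'   matches the decay law of the reference implementation) is the
#'   default.
#' @return an `slx_grid`: `nodes` (n x 3 matrix), `resolution_um`,
#'   `sigma_um`, `radius_um`, `kernel`.
#' @export
build_grid <- function(geometry, radius_um = 40, resolution_um = 5,
                       z_max_um = 100, sigma_um = 40,
                       kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  if (resolution_um <= 0) stop("resolution must be > 0", call. = FALSE)
  pos <- geometry$positions
  z_plane <- pos[1, 3]
  gx <- seq(min(pos[, 1]) - radius_um, max(pos[, 1]) + radius_um,
            by = resolution_um)
  gy <- seq(min(pos[, 2]) - radius_um, max(pos[, 2]) + radius_um,
            by = resolution_um)
  gz <- z_plane + seq(0, z_max_um, by = resolution_um)
  nodes <- as.matrix(expand.grid(x = gx, y = gy, z = gz,
                                 KEEP.OUT.ATTRS = FALSE))
  structure(list(nodes = nodes, resolution_um = resolution_um,
                 sigma_um = sigma_um, radius_um = radius_um,
                 kernel = kernel),
            class = "slx_grid")
}

#' @export
print.slx_grid <- function(x, ...) {
  cat(sprintf("<slx_grid> %d nodes @ %g um, sigma = %s um\n",
              nrow(x$nodes), x$resolution_um,
              paste(x$sigma_um, collapse = "/")))
  invisible(x)
}

# Unit-norm prototype footprints of grid nodes on a channel set: rows =
# nodes, columns = channels. Normalisation makes the similarity a cosine,
# so a footprint proportional to a node's prototype scores highest at
# exactly that node.
gc_prototypes <- function(nodes, channel_positions, sigma_um,
                          kernel = "exponential") {
  D <- cross_dist(nodes, channel_positions)
  A <- if (kernel == "gaussian") exp(-D^2 / (2 * sigma_um^2))
       else exp(-D / sigma_um)
  A / pmax(sqrt(rowSums(A^2)), 1e-300)
}

#' Grid-convolution localization
#'
#' Every grid node within `radius_um` (in the probe plane) of the peak
#' channel gets a prototype footprint on the selected channels —
#' `a_kj = exp(-||p_k - p_j|| / sigma)` by default (see [build_grid()]
#' for the kernel choice) — normalised to unit L2 norm.
#' The similarity `s_k = <ptp, a_k>` (clipped below at 0; the best scale
#' is kept per node when several `sigma_um` are configured) ranks the
#' nodes, and the estimate is the similarity-weighted mean of the nodes
#' whose score reaches the top `percentile_top` percent of positive
#' scores (at least the best node is always used).
#'
#' @inheritParams select_channels
#' @param grid an `slx_grid` from [build_grid()].
#' @param radius_um channel- and node-selection radius (default the
#'   grid's own).
#' @param percentile_top percentage of best-scoring nodes averaged
#'   (default 5).
#' @return an `slx_estimate` with `algorithm = "GC"`; `aux` carries the
#'   total `similarity_mass` over the averaged nodes and their count
#'   `n_top`.
#' @export
localize_gc <- function(ptp, geometry, grid = NULL, radius_um = NULL,
                        percentile_top = 5) {
  grid <- grid %||% build_grid(geometry)
  radius_um <- radius_um %||% grid$radius_um
  sel <- select_channels(ptp, geometry, radius_um)
  idx <- channel_index(geometry, sel$peak_channel)
  peak_xy <- geometry$positions[idx, 1:2]
  nd <- grid$nodes
  near <- (nd[, 1] - peak_xy[1])^2 + (nd[, 2] - peak_xy[2])^2 <=
    radius_um^2
  if (!any(near))
    stop("degenerate signal: no grid nodes near the peak channel",
         call. = FALSE)
  nodes <- nd[near, , drop = FALSE]
  s <- rep(-Inf, nrow(nodes))
  for (sg in grid$sigma_um) {
    A <- gc_prototypes(nodes, sel$positions, sg, grid$kernel %||%
                         "exponential")
    s <- pmax(s, as.vector(A %*% sel$ptp))
  }
  s[s < 0] <- 0
  if (all(s == 0))
    stop("degenerate signal: all node similarities are 0", call. = FALSE)
  thr <- quantile(s[s > 0], probs = 1 - percentile_top / 100,
                  names = FALSE, type = 7)
  top <- which(s >= thr)
  if (length(top) == 0L) top <- which.max(s)
  w <- s[top] / sum(s[top])
  new_estimate(colSums(nodes[top, , drop = FALSE] * w), "GC",
               aux = list(similarity_mass = sum(s[top]),
                          n_top = length(top)))
}

#' Localize a batch of amplitude footprints
#'
#' @param ptp_matrix spikes x channels matrix of peak-to-peak amplitudes
#'   with channel ids as column names; `NA` marks an absent channel for
#'   that spike.
#' @param geometry an `slx_probe`.
#' @param algorithm `"COM"`, `"MT"` or `"GC"`.
#' @param ... passed to the underlying localizer (including `grid` for
#'   GC).
#' @return data.frame with one row per spike: `spike_index`, `algorithm`,
#'   `x`, `y`, `z`, `ok` (FALSE when localization errored), `note`.
#' @export
localize_many <- function(ptp_matrix, geometry,
                          algorithm = c("COM", "MT", "GC"), ...) {
  algorithm <- match.arg(algorithm)
  f <- switch(algorithm, COM = localize_com, MT = localize_mt,
              GC = localize_gc)
  n <- nrow(ptp_matrix)
  out <- data.frame(spike_index = seq_len(n), algorithm = algorithm,
                    x = NA_real_, y = NA_real_, z = NA_real_,
                    ok = FALSE, note = "")
  for (i in seq_len(n)) {
    v <- ptp_matrix[i, ]
    v <- v[!is.na(v)]
    est <- tryCatch(f(v, geometry, ...), error = function(e) e)
    if (inherits(est, "error")) {
      out$note[i] <- conditionMessage(est)
    } else {
      out[i, c("x", "y", "z")] <- as.list(est$position)
      out$ok[i] <- TRUE
    }
  }
  out
}

#' Write location estimates to CSV
#'
#' @param estimates data.frame of estimates (e.g. from [localize_many()]
#'   or the benchmark harness).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  write.csv(estimates, path, row.names = FALSE)
  invisible(path)
}
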