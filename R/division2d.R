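#' Initialize a 2D partition at an exact target ratio
#'
#' The planar division model keeps the area ratio fixed during the
#' whole run, so the initial configuration is generated at the target:
#' `v1 = round(rho_star * N)` sites (round-half-even, R's `round()`)
#' are drawn uniformly at random among the occupied pixels and
#' assigned to daughter 1.
#'
#' @param mask2d A 2D [cell_mask()].
#' @param rho_star Target area ratio in (0, 1).
#' @param seed Optional integer seed.
#' @return A `voxdiv_partition` over the 2D grid.
#' @export
init_partition_at_ratio <- function(mask2d, rho_star, seed = NULL) {
  stopifnot(length(dim(mask2d$occupancy)) == 2,
            rho_star > 0, rho_star < 1)
  if (!is.null(seed)) set.seed(seed)
  occ <- which(mask2d$occupancy)
  N <- length(occ)
  v1 <- as.integer(round(rho_star * N))
  v1 <- max(1L, min(N - 1L, v1))
  lab <- array(0L, dim(mask2d$occupancy))
  lab[occ] <- 2L
  lab[sample(occ, v1)] <- 1L
  partition_from_labels(mask2d, lab)
}

#' Simulate a 2D cell division with ratio-preserving exchange dynamics
#'
#' Planar variant of the division model used for leaf epidermal
#' cells: the energy reduces to the interface term (8-neighborhood
#' unweighted pair counting) and the area ratio is conserved exactly
#' by Kawasaki-type moves that swap the labels of one pixel from each
#' daughter per attempt, accepted by the same Metropolis rule on the
#' interface energy change. The proposal picks one uniformly random
#' pixel from each daughter (not necessarily adjacent).
#'
#' @param mask2d A 2D [cell_mask()].
#' @param params A [model_params()]; `rho_star`, `kT`, `alpha`,
#'   `n_cycles` and `seed` are honored, the volume term is absent by
#'   construction.
#' @param anchor Optional physical point (um), e.g. the nucleus
#'   centroid, for the distance measurement; defaults to the mask
#'   centroid.
#' @return An object of class `voxdiv_division2d`: list with
#'   `partition`, `interface` (list: `length_polyline` um from
#'   marching squares, `length_pairs` um from discordant-pair
#'   counting, `polyline` segment matrix, `anchor_distance` um),
#'   `trace` (per-cycle interface energy), `params`.
#' @export
metropolis_division_2d <- function(mask2d, params = model_params(),
                                   anchor = NULL) {
  stopifnot(length(dim(mask2d$occupancy)) == 2)
  if (is.null(anchor)) anchor <- mask_centroid(mask2d)
  a2 <- resolve_facet_area(params, mask2d)
  init <- init_partition_at_ratio(mask2d, params$rho_star,
                                  seed = params$seed)
  occ_idx <- which(mask2d$occupancy) - 1L
  res <- cpp_metropolis2d_exchange(init$labels, dim(init$labels),
                                   as.integer(occ_idx),
                                   params$alpha * a2 / params$kT,
                                   params$n_cycles,
                                   if (params$quench) 200L else 0L)
  part <- structure(list(labels = res$labels,
                         v1 = as.integer(res$v1), v2 = as.integer(res$v2),
                         n_sites = as.integer(res$n_sites), mask = mask2d),
                    class = "voxdiv_partition")
  iface <- interface_polyline_2d(part)
  adist <- if (nrow(iface$segments) > 0) {
    min(point_segment_distances(anchor[1:2], iface$segments))
  } else NA_real_
  side <- mean(mask2d$calibration$voxel_size)
  structure(list(
    partition = part,
    interface = list(length_polyline = iface$length,
                     length_pairs = res$discordant_pairs * side,
                     polyline = iface$segments,
                     anchor_distance = adist),
    trace = data.frame(cycle = seq_along(res$trace_ha) - 1L,
                       h_a = res$trace_ha),
    params = params), class = "voxdiv_division2d")
}

#' @export
print.voxdiv_division2d <- function(x, ...) {
  cat(sprintf(
    "2D division: rho = %.4f (exact), interface %.3f um (polyline)\n",
    x$partition$v1 / x$partition$n_sites, x$interface$length_polyline))
  invisible(x)
}

# marching-squares polyline of the daughter interface, clipped to the
# mask; returns physical segments (n x 4: x0, y0, x1, y1) and length
interface_polyline_2d <- function(partition) {
  labs <- partition$labels
  dims <- dim(labs)
  ext <- cpp_extend_labels(labs, dims)
  ind <- array(0, dims)
  ind[ext == 1L] <- 1
  # 3x3 box smoothing, edge-replicated
  sm1 <- function(x, d) {
    n <- dim(x)[d]
    lo <- c(1, seq_len(n - 1)); hi <- c(seq_len(n)[-1], n)
    if (d == 1) (x[lo, , drop = FALSE] + x + x[hi, , drop = FALSE]) / 3
    else (x[, lo, drop = FALSE] + x + x[, hi, drop = FALSE]) / 3
  }
  f <- sm1(sm1(ind, 1), 2)
  vs <- partition$mask$calibration$voxel_size
  org <- partition$mask$origin_offset
  cl <- grDevices::contourLines(x = org[1] + (seq_len(dims[1]) - 1) * vs[1],
                                y = org[2] + (seq_len(dims[2]) - 1) * vs[2],
                                z = f, levels = 0.5)
  segs <- NULL
  for (c1 in cl) {
    n <- length(c1$x)
    if (n < 2) next
    segs <- rbind(segs, cbind(c1$x[-n], c1$y[-n], c1$x[-1], c1$y[-1]))
  }
  if (is.null(segs)) return(list(segments = matrix(0, 0, 4), length = 0))
  # clip: keep segments whose midpoint falls in an occupied pixel
  mx <- (segs[, 1] + segs[, 3]) / 2
  my <- (segs[, 2] + segs[, 4]) / 2
  gi <- pmin(dims[1], pmax(1, round((mx - org[1]) / vs[1]) + 1))
  gj <- pmin(dims[2], pmax(1, round((my - org[2]) / vs[2]) + 1))
  keep <- partition$mask$occupancy[cbind(gi, gj)]
  segs <- segs[keep, , drop = FALSE]
  len <- sum(sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2))
  list(segments = segs, length = len)
}

# exact point-to-segment distances (vectorized over segments)
point_segment_distances <- function(p, segs) {
  dx <- segs[, 3] - segs[, 1]; dy <- segs[, 4] - segs[, 2]
  l2 <- dx^2 + dy^2
  t <- ((p[1] - segs[, 1]) * dx + (p[2] - segs[, 2]) * dy) / pmax(l2, 1e-30)
  t <- pmin(1, pmax(0, t))
  qx <- segs[, 1] + t * dx; qy <- segs[, 2] + t * dy
  sqrt((p[1] - qx)^2 + (p[2] - qy)^2)
}
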