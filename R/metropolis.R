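#' Simulate one cell division by Metropolis minimization
#'
#' Runs the stochastic division model on a 3D mother-cell mask:
#' starting from a random assignment of every site to one of the two
#' daughters, single-site reassignments are proposed uniformly at
#' random and accepted whenever they lower the energy
#' `H = H_V + H_A`, or with probability `exp(-dH/kT)` otherwise. One
#' Monte-Carlo cycle is N attempted moves (N = number of sites); the
#' default budget is 5000 cycles. By default the final state is then
#' quenched (zero-temperature descent at fixed realized ratio) so the
#' returned partition is a local minimum of H; see [model_params()].
#'
#' @param mask A 3D [cell_mask()].
#' @param params A [model_params()].
#' @return An object of class `voxdiv_division`: list with
#'   `partition` (a `voxdiv_partition`), `energy` (list `h_v`, `h_a`,
#'   `h_total` of the final state, in kT units), `trace` (data.frame
#'   with one row per cycle: `cycle`, `h_v`, `h_a`, `h_total`),
#'   `params`, and Metropolis acceptance counters `moves`.
#' @examples
#' \donttest{
#' m <- digitize_shape("sphere", radius = 8 * 0.35, calibration(0.35))
#' d <- metropolis_division(m, model_params(rho_star = 0.5, n_cycles = 500))
#' d$partition
#' }
#' @export
metropolis_division <- function(mask, params = model_params()) {
  if (length(dim(mask$occupancy)) != 3)
    stop("metropolis_division expects a 3D mask; see metropolis_division_2d")
  a2 <- resolve_facet_area(params, mask)
  occ_idx <- which(mask$occupancy) - 1L
  set.seed(params$seed)
  p0 <- if (params$init == "half") 0.5 else params$rho_star
  lab <- array(0L, dim(mask$occupancy))
  lab[mask$occupancy] <- ifelse(stats::runif(length(occ_idx)) < p0, 1L, 2L)
  sched <- if (params$init == "half" && params$rho_schedule)
    c(0.3, 0.7) else c(0, 0)
  res <- cpp_metropolis3d(
    lab, dim(lab), as.integer(occ_idx),
    params$rho_star, params$alpha * a2 / params$kT,
    params$n_cycles, params$early_stop, params$early_tol,
    if (params$quench) 500L else 0L, params$quench_band,
    1 / params$kT, sched[1], sched[2], 0.5)
  part <- structure(list(labels = res$labels,
                         v1 = as.integer(res$v1), v2 = as.integer(res$v2),
                         n_sites = as.integer(res$n_sites), mask = mask),
                    class = "voxdiv_partition")
  trace <- data.frame(cycle = seq_along(res$trace_hv) - 1L,
                      h_v = res$trace_hv, h_a = res$trace_ha,
                      h_total = res$trace_hv + res$trace_ha)
  structure(list(
    partition = part,
    # recomputed on the final (post-quench) state; the trace covers the
    # Metropolis phase only
    energy = division_energy(part, params),
    trace = trace,
    cycles_run = res$cycles_run,
    quench_cycles = res$quench_cycles,
    moves = list(down = res$n_down_moves,
                 up_accepted = res$n_up_accepted,
                 up_rejected = res$n_up_rejected),
    params = params), class = "voxdiv_division")
}

#' @export
print.voxdiv_division <- function(x, ...) {
  cat(sprintf(
    "division run: rho* = %g -> realized rho = %.4f, H = %.2f kT (%d cycles)\n",
    x$params$rho_star, x$partition$v1 / x$partition$n_sites,
    x$energy$h_total, x$cycles_run))
  invisible(x)
}

#' Run an ensemble of division simulations on one mother cell
#'
#' Repeats [metropolis_division()] `n_runs` times with independent
#' RNG substreams derived from the base seed, optionally drawing the
#' target volume-ratio of each run uniformly from `rho_range`
#' (the regime used to explore the space of alternative divisions).
#' Each run is measured with [measure_division()] against the given
#' anchor.
#'
#' @param mask A 3D [cell_mask()].
#' @param base_params A [model_params()]; its `seed` is the ensemble
#'   master seed.
#' @param n_runs Number of independent runs.
#' @param rho_mode `"fixed"` (use `base_params$rho_star` everywhere)
#'   or `"uniform_random"` (draw each run's target from `rho_range`).
#' @param rho_range Numeric `(low, high)` within (0, 1), used for
#'   `"uniform_random"`; defaults to the 0.2-0.5 exploration range.
#' @param anchor Physical point (um) for the distance measurement;
#'   defaults to the mask centroid.
#' @param keep_partitions Keep each run's partition object (memory
#'   permitting); required by the nested division rule, which must
#'   re-split the mother along the chosen partition.
#' @return An object of class `voxdiv_ensemble`: list with `measures`
#'   (data.frame, one row per run: run id, substream seed, sampled
#'   rho*, realized volumes, plane measurements) and, when kept,
#'   `partitions` (list of `voxdiv_partition`). The ensemble is
#'   reproducible run-by-run: run i depends only on
#'   `(base seed, i)`.
#' @export
run_ensemble <- function(mask, base_params = model_params(), n_runs = 40,
                         rho_mode = c("fixed", "uniform_random"),
                         rho_range = c(0.2, 0.5),
                         anchor = NULL, keep_partitions = TRUE) {
  rho_mode <- match.arg(rho_mode)
  stopifnot(n_runs >= 1)
  if (rho_mode == "uniform_random") {
    stopifnot(length(rho_range) == 2, rho_range[1] > 0,
              rho_range[2] > rho_range[1], rho_range[2] < 1)
  }
  if (is.null(anchor)) anchor <- mask_centroid(mask)
  rows <- vector("list", n_runs)
  parts <- if (keep_partitions) vector("list", n_runs) else NULL
  for (i in seq_len(n_runs)) {
    seed_i <- derive_seed(base_params$seed, i)
    rho_i <- if (rho_mode == "fixed") base_params$rho_star else {
      set.seed(derive_seed(seed_i, 999L))
      stats::runif(1, rho_range[1], rho_range[2])
    }
    p <- base_params
    p$seed <- seed_i
    p$rho_star <- rho_i
    div <- metropolis_division(mask, p)
    meas <- if (div$partition$v1 == 0L || div$partition$v2 == 0L) {
      # degenerate run (one daughter invaded the whole cell): recorded
      # with NA plane measures so downstream filters can exclude it
      degenerate_measures_row(div$partition)
    } else {
      measure_division(div$partition, anchor = anchor)
    }
    rows[[i]] <- cbind(data.frame(run = i, seed = seed_i,
                                  rho_star = rho_i), meas)
    if (keep_partitions) parts[[i]] <- div$partition
  }
  structure(list(measures = do.call(rbind, rows), partitions = parts,
                 mask = mask, anchor = anchor,
                 base_seed = base_params$seed, rho_mode = rho_mode),
            class = "voxdiv_ensemble")
}

#' @export
print.voxdiv_ensemble <- function(x, ...) {
  cat(sprintf("division ensemble: %d runs (%s rho*), master seed %d\n",
              nrow(x$measures), x$rho_mode, x$base_seed))
  invisible(x)
}

#' @export
as.data.frame.voxdiv_ensemble <- function(x, ...) x$measures

# measures row for a division with no interface (all plane-level
# fields NA, fragmentation counts set so rules always exclude it)
degenerate_measures_row <- function(partition) {
  data.frame(area = NA_real_, normal_x = NA_real_, normal_y = NA_real_,
             normal_z = NA_real_, centroid_x = NA_real_,
             centroid_y = NA_real_, centroid_z = NA_real_,
             anchor_distance = Inf, orientation_angle = NA_real_,
             degenerate_normal = TRUE,
             v1 = partition$v1, v2 = partition$v2,
             realized_rho = partition$v1 / partition$n_sites,
             rho_smallest = min(partition$v1, partition$v2) /
               partition$n_sites,
             n_components_d1 = NA_integer_, n_components_d2 = NA_integer_)
}
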