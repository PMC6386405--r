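#' Partitions of a mother cell
#'
#' A partition assigns every occupied site of a mother-cell mask to
#' daughter 1 or daughter 2. Internally stored as an integer grid with
#' 0 outside the mask and 1/2 on occupied sites, plus cached daughter
#' volumes (in sites).
#'
#' @param mask A [cell_mask()].
#' @param labels Integer array matching the mask grid, with values 1 or
#'   2 exactly on occupied sites and 0 elsewhere.
#' @return An object of class `voxdiv_partition` with elements
#'   `labels`, `v1`, `v2`, `n_sites`, `mask`.
#' @export
partition_from_labels <- function(mask, labels) {
  if (!identical(dim(labels), dim(mask$occupancy)))
    stop("labels grid does not match the mask grid")
  labels <- array(as.integer(labels), dim(labels))
  if (any(labels[!mask$occupancy] != 0L))
    stop("labels must be 0 outside the mask")
  on <- labels[mask$occupancy]
  if (any(!on %in% c(1L, 2L)))
    stop("occupied sites must carry label 1 or 2")
  structure(list(labels = labels,
                 v1 = sum(on == 1L), v2 = sum(on == 2L),
                 n_sites = length(on), mask = mask),
            class = "voxdiv_partition")
}

#' Random initial partition
#'
#' Assigns each occupied site independently to daughter 1 with
#' probability `p` (Bernoulli), the initial condition of the Metropolis
#' division dynamics.
#'
#' @param mask A [cell_mask()].
#' @param p Probability of daughter 1 per site.
#' @param seed Optional integer seed (uses the current RNG state when
#'   `NULL`).
#' @return A `voxdiv_partition`.
#' @export
random_partition <- function(mask, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lab <- array(0L, dim(mask$occupancy))
  lab[mask$occupancy] <- ifelse(stats::runif(site_count(mask)) < p, 1L, 2L)
  partition_from_labels(mask, lab)
}

#' @export
print.voxdiv_partition <- function(x, ...) {
  cat(sprintf("partition: %d sites -> v1 = %d, v2 = %d (rho = %.4f)\n",
              x$n_sites, x$v1, x$v2, x$v1 / x$n_sites))
  invisible(x)
}

#' Division-energy terms
#'
#' `volume_energy()` is the volume-ratio constraint
#' \eqn{H_V = ([V_1 - \rho^* V]^2 + [V_2 - (1-\rho^*) V]^2)^{1/3}}
#' (volumes in sites); it is zero exactly when the realized split
#' matches the target. `interface_energy()` is
#' \eqn{H_A = \alpha a^2 D} with \eqn{D} the number of unordered
#' neighbor pairs (26-neighborhood in 3D, 8 in 2D) whose sites belong
#' to different daughters; it is zero only for a single-label
#' partition. `division_energy()` returns the full breakdown.
#'
#' @param partition A `voxdiv_partition`.
#' @param params A [model_params()].
#' @return Energy in kT units (scalar), or for `division_energy()` a
#'   list with `h_v`, `h_a`, `h_total`.
#' @export
volume_energy <- function(partition, params) {
  N <- partition$n_sites
  t1 <- partition$v1 - params$rho_star * N
  t2 <- partition$v2 - (1 - params$rho_star) * N
  (t1^2 + t2^2)^(1 / 3) / params$kT
}

#' @rdname volume_energy
#' @export
interface_energy <- function(partition, params) {
  D <- cpp_count_discordant_pairs(partition$labels, dim(partition$labels))
  a2 <- resolve_facet_area(params, partition$mask)
  params$alpha * a2 * D / params$kT
}

#' @rdname volume_energy
#' @export
division_energy <- function(partition, params) {
  h_v <- volume_energy(partition, params)
  h_a <- interface_energy(partition, params)
  list(h_v = h_v, h_a = h_a, h_total = h_v + h_a)
}

#' Local energy change of a single-site move
#'
#' Energy difference that would result from assigning `site` to the
#' other daughter, computed locally: only the site's (at most 26)
#' neighbor facets and the two volume counts enter. Agrees with a full
#' recomputation of `division_energy()` to floating-point precision.
#'
#' @param partition A `voxdiv_partition`.
#' @param site Site index: either a single linear index into the grid
#'   or a vector of grid coordinates (1-based).
#' @param params A [model_params()].
#' @return The energy change `dH` in kT units.
#' @export
delta_energy <- function(partition, site, params) {
  dims <- dim(partition$labels)
  if (length(site) == length(dims)) {
    site <- sum((site - 1) * cumprod(c(1, dims[-length(dims)]))) + 1
  }
  site <- as.integer(site)
  if (site < 1 || site > length(partition$labels) ||
      partition$labels[site] == 0L)
    stop("site is outside the mother-cell mask")
  dD <- cpp_toggle_delta_pairs(partition$labels, dims, site - 1L)
  a2 <- resolve_facet_area(params, partition$mask)
  l <- partition$labels[site]
  nv1 <- if (l == 1L) partition$v1 - 1L else partition$v1 + 1L
  N <- partition$n_sites
  hv <- function(v1) {
    ((v1 - params$rho_star * N)^2 +
       ((N - v1) - (1 - params$rho_star) * N)^2)^(1 / 3)
  }
  (params$alpha * a2 * dD + hv(nv1) - hv(partition$v1)) / params$kT
}

# apply a single-site toggle, keeping caches consistent
toggle_site <- function(partition, site) {
  l <- partition$labels[site]
  stopifnot(l %in% c(1L, 2L))
  partition$labels[site] <- 3L - l
  if (l == 1L) {
    partition$v1 <- partition$v1 - 1L; partition$v2 <- partition$v2 + 1L
  } else {
    partition$v1 <- partition$v1 + 1L; partition$v2 <- partition$v2 - 1L
  }
  partition
}

#' Connected components of the daughters
#'
#' Face-connectivity component counts of each daughter region; a
#' biologically meaningful division has one component per daughter.
#' Values above 1 flag fragmented solutions, which the rule-evaluation
#' machinery excludes.
#'
#' @param partition A `voxdiv_partition`.
#' @return Integer vector `c(d1, d2)`.
#' @export
daughter_components <- function(partition) {
  c(d1 = cpp_count_components(partition$labels, dim(partition$labels), 1L),
    d2 = cpp_count_components(partition$labels, dim(partition$labels), 2L))
}
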