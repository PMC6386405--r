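#' Division-model parameters
#'
#' Parameters of the discrete-space division energy
#' \deqn{H(x) = H_V(x) + H_A(x)}
#' with the volume-ratio term
#' \deqn{H_V(x) = ([V_1(x) - V_1^*]^2 + [V_2(x) - V_2^*]^2)^{1/3},}
#' where \eqn{V_1, V_2} are daughter volumes in lattice sites,
#' \eqn{V_1^* = \rho^* V}, \eqn{V_2^* = (1 - \rho^*) V}, and the
#' interface term
#' \deqn{H_A(x) = \alpha\, a^2 \sum_{(i,j)\ \mathrm{neighbors}}
#'   \mathbf{1}[x_i \ne x_j],}
#' summed once over unordered 26-neighborhood pairs, with \eqn{a} the
#' voxel side so that \eqn{a^2} is the facet area (um^2). The Metropolis
#' acceptance uses `exp(-dH / kT)`.
#'
#' `kT` sets the exploration noise relative to the two constraint
#' terms. With the default calibration (cubic 0.35 um) and
#' `kT = 0.25`, a discordant neighbor pair costs about 1 kT and a
#' one-site volume-ratio violation about 3.4 kT, which keeps daughter
#' volumes pinned at the target ratio while letting the interface
#' anneal to a smooth near-minimal surface within the default cycle
#' budget. See the package vignette for how this operating point was
#' chosen and what happens in the too-hot (fragmented, "noisy") and
#' too-cold (one daughter invades, "degenerate") regimes.
#'
#' @param rho_star Target volume-ratio in (0, 1); 0.5 simulates a
#'   symmetric division.
#' @param alpha Balance parameter between volume and interface terms;
#'   fixed to 2 in all reference simulations.
#' @param facet_area Area of one voxel facet in um^2; defaults to
#'   `side^2` from the calibration supplied at run time (`NULL`).
#' @param kT Energy scale of the Metropolis acceptance.
#' @param n_cycles Monte-Carlo cycles; one cycle is N attempted
#'   single-site moves, N the number of mother-cell sites.
#' @param seed Integer RNG seed; every simulation entry point is fully
#'   reproducible given the seed.
#' @param init One of `"half"` (each site assigned to either daughter
#'   with probability 1/2, the default) or `"rho"` (daughter 1 with
#'   probability `rho_star`). With the unbiased default the volume term
#'   drags the single coarsened interface to the target ratio;
#'   initializing at a strongly asymmetric ratio tends to scatter the
#'   minority phase into droplets that dissolve.
#' @param early_stop If `TRUE`, stop when the 100-cycle moving average
#'   of H changes by less than `early_tol` (relative).
#' @param early_tol Relative tolerance for `early_stop`.
#' @param quench If `TRUE` (default), finish with a zero-temperature
#'   descent (accept only energy-lowering moves, realized volumes held
#'   within `quench_band` sites), so the reported partition is a local
#'   minimum of H rather than one thermal sample: detached bubbles
#'   dissolve and lattice-scale roughness flattens. Set to `FALSE` to
#'   obtain the raw final Metropolis state.
#' @param quench_band Maximum drift (sites) of the daughter-1 volume
#'   during the quench.
#' @param rho_schedule With the default unbiased initialization, hold
#'   the target ratio at 0.5 over the first 30% of cycles (while the
#'   random state coarsens into one compact interface) and slide it
#'   linearly to `rho_star` between 30% and 70%, holding `rho_star`
#'   thereafter. This continuation keeps the minority daughter
#'   connected at strongly asymmetric targets; disable to apply the
#'   final target from cycle 0.
#' @return An object of class `voxdiv_params`.
#' @export
model_params <- function(rho_star = 0.5, alpha = 2, facet_area = NULL,
                         kT = 0.25, n_cycles = 5000, seed = 1,
                         init = c("half", "rho"),
                         early_stop = FALSE, early_tol = 1e-6,
                         quench = TRUE, quench_band = 2L,
                         rho_schedule = TRUE) {
  stopifnot(rho_star > 0, rho_star < 1, alpha > 0, kT > 0, n_cycles >= 1)
  if (!is.null(facet_area)) stopifnot(facet_area > 0)
  structure(list(rho_star = rho_star, alpha = alpha,
                 facet_area = facet_area, kT = kT,
                 n_cycles = as.integer(n_cycles), seed = as.integer(seed),
                 init = match.arg(init),
                 early_stop = early_stop, early_tol = early_tol,
                 quench = quench, quench_band = as.integer(quench_band),
                 rho_schedule = rho_schedule),
            class = "voxdiv_params")
}

#' @export
print.voxdiv_params <- function(x, ...) {
  cat(sprintf(
    "division model: rho* = %g, alpha = %g, kT = %g, %d cycles, seed %d\n",
    x$rho_star, x$alpha, x$kT, x$n_cycles, x$seed))
  invisible(x)
}

# facet area actually used for a given mask (um^2)
resolve_facet_area <- function(params, mask) {
  if (!is.null(params$facet_area)) return(params$facet_area)
  vs <- mask$calibration$voxel_size
  if (!is_cubic(mask$calibration))
    warning("anisotropic calibration: using the mean edge for the facet area")
  mean(vs)^2
}

# derive a per-run 32-bit substream seed from (master seed, index);
# splitmix-style integer hash, order-independent across runs
derive_seed <- function(master, index) {
  x <- (as.numeric(master) * 2654435761 + as.numeric(index) * 40503 +
          1013904223) %% 2^31
  as.integer(x)
}
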