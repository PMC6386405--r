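#' Relative measure of a solution within a reference set
#'
#' Normalization used to pool plane measurements across cells of
#' different sizes: the relative measure of a value `x` against a
#' reference set S is the proportion of reference values strictly
#' smaller than `x`,
#' \deqn{\hat{A}(x) = \frac{1}{|S|} \sum_{x' \in S} \mathbf{1}[A(x') < A(x)].}
#' It lies in [0, 1] by construction and is uniformly distributed on
#' [0, 1] when `x` is statistically equivalent to the references. Ties
#' do not count (strict inequality); a midrank variant (ties count
#' 1/2) is available for sensitivity analysis.
#'
#' @param x_value Scalar measurement (e.g. plane area or distance).
#' @param reference_values Nonempty numeric vector of alternative
#'   measurements from the same cell.
#' @param regime Optional tag describing how the reference set was
#'   generated (e.g. `"observed_rho"`, `"random_rho"`).
#' @param ties `"strict"` (default, as defined) or `"midrank"`.
#' @return An object of class `voxdiv_relative_measure`: list with
#'   `value`, `reference_set_size`, `regime`, `ties`.
#' @export
relative_measure <- function(x_value, reference_values, regime = NULL,
                             ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  if (length(reference_values) == 0)
    stop("reference set is empty")
  stopifnot(is.finite(x_value), all(is.finite(reference_values)))
  v <- if (ties == "strict") {
    mean(reference_values < x_value)
  } else {
    mean(reference_values < x_value) + 0.5 * mean(reference_values == x_value)
  }
  structure(list(value = v,
                 reference_set_size = length(reference_values),
                 regime = regime, ties = ties),
            class = "voxdiv_relative_measure")
}

#' @export
print.voxdiv_relative_measure <- function(x, ...) {
  cat(sprintf("relative measure: %.3f (|S| = %d%s)\n", x$value,
              x$reference_set_size,
              if (is.null(x$regime)) "" else paste0(", ", x$regime)))
  invisible(x)
}

# vectorized strict relative measures (used internally)
relative_values <- function(x, refs) {
  vapply(x, function(v) mean(refs < v), 0)
}

#' Classify a division plane in the embryo coordinate frame
#'
#' Assigns an orientation class to a measured division plane by
#' thresholding the angle between its unit normal and three reference
#' directions derived from the embryo frame and the cell position:
#' the radial direction (from the frame origin toward the cell
#' centroid) for periclinal planes, the apical-basal `k` axis for
#' transverse planes, and the tangential direction (`k` cross radial)
#' for longitudinal anticlinal planes. A plane within `cone_deg` of
#' none of the references (or with a degenerate normal) is classified
#' `"other"`. The classification operationalizes what the original
#' analyses did visually; the cone half-angle is configurable.
#'
#' @param measures One-row data.frame from [measure_division()] (needs
#'   `normal_x/y/z`).
#' @param frame An [build_embryo_frame()] result.
#' @param cell_centroid Physical centroid (um) of the mother cell.
#' @param partition Optional `voxdiv_partition` used to derive the
#'   size-polarity tag (which daughter is larger and whether it sits
#'   on the apical or basal side along `k`).
#' @param cone_deg Cone half-angle in degrees (default 30).
#' @return List with `class` (one of `"periclinal"`,
#'   `"anticlinal_longitudinal"`, `"transverse"`, `"other"`),
#'   `angles` (named vector of the three reference angles) and
#'   `polarity` (`"larger_apical"`, `"larger_basal"` or `NA`).
#' @export
classify_candidate <- function(measures, frame, cell_centroid,
                               partition = NULL, cone_deg = 30) {
  normal <- c(measures$normal_x, measures$normal_y, measures$normal_z)
  if (any(!is.finite(normal)))
    return(list(class = "other",
                angles = c(periclinal = NA, transverse = NA,
                           longitudinal = NA),
                polarity = NA_character_))
  radial <- cell_centroid - frame$origin
  radial_t <- radial - sum(radial * frame$k_axis) * frame$k_axis
  if (sqrt(sum(radial_t^2)) < 1e-9) radial_t <- frame$i_axis
  radial_t <- radial_t / sqrt(sum(radial_t^2))
  tangential <- c(
    frame$k_axis[2] * radial_t[3] - frame$k_axis[3] * radial_t[2],
    frame$k_axis[3] * radial_t[1] - frame$k_axis[1] * radial_t[3],
    frame$k_axis[1] * radial_t[2] - frame$k_axis[2] * radial_t[1])
  tangential <- tangential / sqrt(sum(tangential^2))
  angles <- c(periclinal = inter_plane_angle(normal, radial_t),
              transverse = inter_plane_angle(normal, frame$k_axis),
              longitudinal = inter_plane_angle(normal, tangential))
  cls <- if (min(angles) > cone_deg) "other" else
    c("periclinal", "transverse", "anticlinal_longitudinal")[which.min(angles)]
  polarity <- NA_character_
  if (!is.null(partition)) {
    cts <- daughter_centroids(partition)
    larger <- if (partition$v1 >= partition$v2) cts$d1 else cts$d2
    smaller <- if (partition$v1 >= partition$v2) cts$d2 else cts$d1
    polarity <- if (sum((larger - smaller) * frame$k_axis) > 0)
      "larger_apical" else "larger_basal"
  }
  list(class = cls, angles = angles, polarity = polarity)
}

# physical centroids of the two daughters
daughter_centroids <- function(partition) {
  m <- partition$mask
  i1 <- which(partition$labels == 1L, arr.ind = TRUE)
  i2 <- which(partition$labels == 2L, arr.ind = TRUE)
  list(d1 = grid_to_phys(colMeans(i1), m), d2 = grid_to_phys(colMeans(i2), m))
}

#' Select a division by the nested centroid-then-area rule
#'
#' The geometrical division rule: among candidate solutions whose
#' plane passes through or close to the anchor (anchor distance below
#' a threshold of about one voxel), select the one of least interface
#' area.
#' Candidates with fragmented daughters are excluded before the
#' distance filter. Ties are broken by lower anchor distance, then by
#' lower run seed, so the choice is deterministic and independent of
#' candidate order. When no candidate passes the distance filter the
#' result explicitly reports `"no_admissible_solution"`; there is no
#' silent fallback.
#'
#' @param candidates A `voxdiv_ensemble` or its `measures`
#'   data.frame (needs columns `area`, `anchor_distance`,
#'   `n_components_d1`, `n_components_d2`, `seed`).
#' @param threshold Admissibility radius in um. The recursive embryo
#'   simulation uses one voxel diagonal (0.61 um at the reference
#'   calibration), the resolution limit of the discrete
#'   centroid-distance measurement; pass one voxel side for a stricter
#'   variant.
#' @param anchor Unused when `candidates` carries measures already
#'   computed against the intended anchor; kept explicit for audit.
#' @return An object of class `voxdiv_rule_choice`: list with
#'   `status` (`"ok"` or `"no_admissible_solution"`), `chosen_index`
#'   (row index into the candidate table, NA if none), `chosen` (the
#'   row), and `audit`, a data.frame recording for every candidate
#'   whether it was excluded and why (`fragmented`,
#'   `too_far`, `not_minimal`, `chosen`).
#' @export
select_by_nested_rule <- function(candidates, threshold, anchor = NULL) {
  meas <- if (inherits(candidates, "voxdiv_ensemble"))
    candidates$measures else candidates
  if (nrow(meas) == 0) stop("candidate set is empty")
  if (!"seed" %in% names(meas)) meas$seed <- seq_len(nrow(meas))
  frag <- is.na(meas$n_components_d1) | is.na(meas$n_components_d2) |
    meas$n_components_d1 > 1 | meas$n_components_d2 > 1
  near <- meas$anchor_distance < threshold
  admissible <- which(!frag & near)
  audit <- data.frame(candidate = seq_len(nrow(meas)),
                      seed = meas$seed,
                      area = meas$area,
                      anchor_distance = meas$anchor_distance,
                      status = ifelse(frag, "fragmented",
                                      ifelse(!near, "too_far",
                                             "not_minimal")))
  if (length(admissible) == 0) {
    return(structure(list(status = "no_admissible_solution",
                          chosen_index = NA_integer_, chosen = NULL,
                          audit = audit),
                     class = "voxdiv_rule_choice"))
  }
  sub <- meas[admissible, ]
  ord <- order(sub$area, sub$anchor_distance, sub$seed)
  chosen <- admissible[ord[1]]
  audit$status[chosen] <- "chosen"
  structure(list(status = "ok", chosen_index = chosen,
                 chosen = meas[chosen, ], audit = audit),
            class = "voxdiv_rule_choice")
}

#' @export
print.voxdiv_rule_choice <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "nested rule: candidate %d chosen (area %.3f um^2, distance %.3f um)\n",
      x$chosen_index, x$chosen$area, x$chosen$anchor_distance))
  } else {
    cat("nested rule: no admissible solution\n")
  }
  invisible(x)
}

#' Compare concordant solutions with reference regimes
#'
#' For each concordant candidate and each reference regime, computes
#' the relative area and relative anchor distance against that
#' regime's solution set. A regime named (or tagged)
#' `"random_rho_centroid_constrained"` restricts, per candidate, the
#' references to those passing at least as close to the anchor as the
#' candidate itself ("planes passing as close to cell centroids"); if
#' that constrained subset is empty the candidate is skipped with a
#' warning.
#'
#' @param concordant data.frame of concordant candidate measures
#'   (columns `area`, `anchor_distance`).
#' @param regimes Named list of reference measure data.frames (same
#'   columns).
#' @param constrained_regimes Character vector of regime names to
#'   treat as centroid-constrained.
#' @return Long data.frame: `candidate`, `regime`, `relative_area`,
#'   `relative_distance`, `n_reference`.
#' @export
ensemble_comparison <- function(concordant, regimes,
                                constrained_regimes =
                                  "random_rho_centroid_constrained") {
  stopifnot(nrow(concordant) >= 1, length(regimes) >= 1,
            !is.null(names(regimes)))
  out <- list()
  for (rg in names(regimes)) {
    refs <- regimes[[rg]]
    if (nrow(refs) == 0) stop("regime ", rg, " has an empty reference set")
    for (i in seq_len(nrow(concordant))) {
      r <- refs
      if (rg %in% constrained_regimes) {
        r <- refs[refs$anchor_distance <= concordant$anchor_distance[i], ]
        if (nrow(r) == 0) {
          warning("candidate ", i, ": empty constrained reference set in ",
                  rg, "; skipped")
          next
        }
      }
      out[[length(out) + 1]] <- data.frame(
        candidate = i, regime = rg,
        relative_area = mean(r$area < concordant$area[i]),
        relative_distance =
          mean(r$anchor_distance < concordant$anchor_distance[i]),
        n_reference = nrow(r))
    }
  }
  do.call(rbind, out)
}
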