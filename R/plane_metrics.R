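#' Geometric summary of a division plane
#'
#' Computes the plane-level quantities used throughout the analysis:
#' total mesh area; the unit normal as the area-weighted average of
#' facet normals (oriented from daughter 1 toward daughter 2); the
#' mesh centroid as the projection of the area-weighted mean of
#' triangle centroids onto the mesh; the anchor distance as the exact
#' minimum Euclidean distance from the anchor point to the mesh
#' surface (point-to-triangle projection, not vertex-only); and, when
#' a reference direction is given, the absolute angle between the
#' plane normal and that direction, folded to [0, 90] degrees so the
#' normal sign convention never affects results.
#'
#' @param mesh A `voxdiv_mesh` from [extract_interface_mesh()].
#' @param anchor Physical point (um), typically the mother-cell
#'   centroid or a nucleus centroid.
#' @param reference_vector Optional unit 3-vector for the orientation
#'   angle.
#' @return A one-row data.frame with columns `area`, `normal_x/y/z`,
#'   `centroid_x/y/z`, `anchor_distance`, `orientation_angle` (NA
#'   without a reference vector or for a degenerate normal),
#'   `degenerate_normal`.
#' @export
plane_summary <- function(mesh, anchor, reference_vector = NULL) {
  stopifnot(inherits(mesh, "voxdiv_mesh"), length(anchor) == 3,
            all(is.finite(anchor)))
  A <- sum(mesh$areas)
  wn <- colSums(mesh$normals * mesh$areas)
  nn <- sqrt(sum(wn^2))
  degenerate <- nn < 1e-6 * A
  unit_normal <- if (degenerate) c(NA_real_, NA_real_, NA_real_) else wn / nn
  # area-weighted mean of triangle centroids, projected onto the mesh
  tc <- (mesh$soup[, 1:3, drop = FALSE] + mesh$soup[, 4:6, drop = FALSE] +
           mesh$soup[, 7:9, drop = FALSE]) / 3
  gbar <- colSums(tc * mesh$areas) / A
  proj <- cpp_point_mesh_distance(gbar, mesh$soup)
  centroid <- proj$closest
  adist <- cpp_point_mesh_distance(as.numeric(anchor), mesh$soup)$distance
  ang <- NA_real_
  if (!is.null(reference_vector) && !degenerate) {
    ang <- inter_plane_angle(unit_normal, reference_vector)
  }
  data.frame(area = A,
             normal_x = unit_normal[1], normal_y = unit_normal[2],
             normal_z = unit_normal[3],
             centroid_x = centroid[1], centroid_y = centroid[2],
             centroid_z = centroid[3],
             anchor_distance = adist,
             orientation_angle = ang,
             degenerate_normal = degenerate)
}

#' Volume ratio of a division
#'
#' Ratio between the volume of one daughter and the mother volume.
#' The daughter is selected either as the smallest one (the
#' convention for stages without spatial annotation) or explicitly by
#' label.
#'
#' @param partition A `voxdiv_partition` with both daughters
#'   nonempty.
#' @param selection `"smallest"` or `"by_region"`.
#' @param region_label Daughter label (1 or 2) to select when
#'   `selection = "by_region"`.
#' @return The ratio in (0, 1); at most 0.5 for `"smallest"`.
#' @export
volume_ratio <- function(partition, selection = c("smallest", "by_region"),
                         region_label = NULL) {
  selection <- match.arg(selection)
  if (partition$v1 == 0L || partition$v2 == 0L)
    stop("both daughters must be nonempty")
  if (selection == "smallest")
    return(min(partition$v1, partition$v2) / partition$n_sites)
  if (is.null(region_label))
    stop("selection = \"by_region\" requires region_label")
  stopifnot(region_label %in% c(1, 2))
  v <- if (region_label == 1) partition$v1 else partition$v2
  v / partition$n_sites
}

#' Angle between two division-plane normals
#'
#' Orientation-free angle in [0, 90] degrees: antiparallel normals
#' give 0.
#'
#' @param normal_a,normal_b Unit 3-vectors.
#' @return Angle in degrees.
#' @export
inter_plane_angle <- function(normal_a, normal_b) {
  na <- sqrt(sum(normal_a^2)); nb <- sqrt(sum(normal_b^2))
  if (na < 1e-12 || nb < 1e-12) stop("zero-length normal vector")
  ct <- abs(sum(normal_a * normal_b)) / (na * nb)
  acos(pmin(1, ct)) * 180 / pi
}

#' Full measurement of one simulated division
#'
#' Convenience wrapper that extracts the interface mesh and assembles
#' the complete per-division record: plane geometry
#' ([plane_summary()]), realized volumes and volume-ratio, and
#' daughter fragmentation counts.
#'
#' @param partition A `voxdiv_partition`.
#' @param anchor Physical anchor point (um); defaults to the mother
#'   mask centroid.
#' @param reference_vector Optional reference direction for the
#'   orientation angle.
#' @return One-row data.frame combining the [plane_summary()] columns
#'   with `v1`, `v2`, `realized_rho` (= v1 / N), `rho_smallest`,
#'   `n_components_d1`, `n_components_d2`.
#' @export
measure_division <- function(partition, anchor = NULL,
                             reference_vector = NULL) {
  if (is.null(anchor)) anchor <- mask_centroid(partition$mask)
  mesh <- extract_interface_mesh(partition)
  ps <- plane_summary(mesh, anchor, reference_vector)
  comp <- daughter_components(partition)
  cbind(ps, data.frame(
    v1 = partition$v1, v2 = partition$v2,
    realized_rho = partition$v1 / partition$n_sites,
    rho_smallest = min(partition$v1, partition$v2) / partition$n_sites,
    n_components_d1 = comp[["d1"]], n_components_d2 = comp[["d2"]]))
}
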