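#' Extract the division interface as a triangular mesh
#'
#' Builds the triangulated surface separating the two daughters of a
#' partition, the object on which all plane-level measurements (area,
#' normal, centroid, distances) are made. The daughter-1 indicator is
#' first extended into the background (so the surface continues
#' smoothly past the mother wall), box-smoothed over a 3x3x3
#' neighborhood, and the 0.5-level surface is extracted by marching
#' tetrahedra with linear edge interpolation; triangles are then
#' clipped back to the mother-cell interior, which excludes the outer
#' wall from the mesh. Smoothing the scalar field removes the
#' staircase bias of iso-surfacing a binary grid (up to ~70% area
#' overestimation for oblique planes); no smoothing is applied to the
#' mesh itself. If the smoothed field has no 0.5-crossing (possible
#' for daughters one voxel thick) the raw binary indicator is used
#' instead.
#'
#' Triangle winding is chosen so normals point from daughter 1 toward
#' daughter 2.
#'
#' @param partition A `voxdiv_partition` with both daughters nonempty.
#' @param smooth Box-smooth the indicator before extraction (default
#'   `TRUE`).
#' @return An object of class `voxdiv_mesh`: list with `vertices`
#'   (n x 3 matrix, um), `triangles` (m x 3 index matrix), `areas`
#'   (per-triangle, um^2), `normals` (per-triangle unit normals).
#' @export
extract_interface_mesh <- function(partition, smooth = TRUE) {
  if (partition$v1 == 0L || partition$v2 == 0L)
    stop("no interface: partition has a single label")
  labs <- partition$labels
  dims <- dim(labs)
  if (length(dims) != 3)
    stop("mesh extraction applies to 3D partitions")
  ext <- cpp_extend_labels(labs, dims)
  ind <- array(0, dims)
  ind[ext == 1L] <- 1
  field <- if (smooth) box_smooth3(ind) else ind
  mask <- partition$mask
  tri <- cpp_march_interface(as.numeric(field),
                             storage_labels(mask$occupancy), dims,
                             mask$calibration$voxel_size,
                             mask$origin_offset, 0.5)
  if (nrow(tri) == 0 && smooth) {
    tri <- cpp_march_interface(as.numeric(ind),
                               storage_labels(mask$occupancy), dims,
                               mask$calibration$voxel_size,
                               mask$origin_offset, 0.5)
  }
  if (nrow(tri) == 0)
    stop("no interface: isosurface extraction produced no triangles")
  mesh_from_soup(tri)
}

# 3^3 box filter with edge replication, separable
box_smooth3 <- function(a) {
  sm1 <- function(x, d) {
    n <- dim(x)[d]
    idx_lo <- c(1, seq_len(n - 1))
    idx_hi <- c(seq_len(n)[-1], n)
    slice <- function(i) {
      switch(d,
             x[i, , , drop = FALSE],
             x[, i, , drop = FALSE],
             x[, , i, drop = FALSE])
    }
    (slice(idx_lo) + slice(seq_len(n)) + slice(idx_hi)) / 3
  }
  sm1(sm1(sm1(a, 1), 2), 3)
}

# triangle soup (n x 9) -> indexed mesh with per-triangle areas/normals
mesh_from_soup <- function(tri) {
  v <- rbind(tri[, 1:3, drop = FALSE], tri[, 4:6, drop = FALSE],
             tri[, 7:9, drop = FALSE])
  key <- paste(round(v[, 1], 9), round(v[, 2], 9), round(v[, 3], 9))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  vertices <- v[uk, , drop = FALSE]
  n <- nrow(tri)
  triangles <- cbind(vid[seq_len(n)], vid[n + seq_len(n)],
                     vid[2 * n + seq_len(n)])
  u <- tri[, 4:6, drop = FALSE] - tri[, 1:3, drop = FALSE]
  w <- tri[, 7:9, drop = FALSE] - tri[, 1:3, drop = FALSE]
  cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
              u[, 3] * w[, 1] - u[, 1] * w[, 3],
              u[, 1] * w[, 2] - u[, 2] * w[, 1])
  areas <- 0.5 * sqrt(rowSums(cr^2))
  keep <- areas > 1e-12
  structure(list(vertices = vertices,
                 triangles = triangles[keep, , drop = FALSE],
                 areas = areas[keep],
                 normals = cr[keep, , drop = FALSE] / (2 * areas[keep]),
                 soup = tri[keep, , drop = FALSE]),
            class = "voxdiv_mesh")
}

#' @export
print.voxdiv_mesh <- function(x, ...) {
  cat(sprintf("division mesh: %d vertices, %d triangles, area %.3f um^2\n",
              nrow(x$vertices), nrow(x$triangles), sum(x$areas)))
  invisible(x)
}

#' Total mesh area (um^2)
#' @param mesh A `voxdiv_mesh`.
#' @export
mesh_area <- function(mesh) sum(mesh$areas)

#' Export a mesh to PLY or OFF
#'
#' Plain-text formats readable by standard 3D viewers (MeshLab,
#' ParaView).
#'
#' @param mesh A `voxdiv_mesh`.
#' @param path Output file; format chosen by extension `.ply` or
#'   `.off`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  nv <- nrow(mesh$vertices); nt <- nrow(mesh$triangles)
  if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nv),
             "property float x", "property float y", "property float z",
             paste("element face", nt),
             "property list uchar int vertex_indices", "end_header")
    vl <- apply(mesh$vertices, 1, function(r) paste(signif(r, 8), collapse = " "))
    fl <- apply(mesh$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " "))
    writeLines(c(hdr, vl, fl), path)
  } else if (ext == "off") {
    vl <- apply(mesh$vertices, 1, function(r) paste(signif(r, 8), collapse = " "))
    fl <- apply(mesh$triangles - 1L, 1, function(r) paste(c(3, r), collapse = " "))
    writeLines(c("OFF", paste(nv, nt, 0), vl, fl), path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
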