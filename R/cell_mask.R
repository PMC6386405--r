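#' Cell mask: a calibrated binary occupancy grid
#'
#' The basic spatial container: one mother cell represented as a boolean
#' 3D array (or 2D matrix) of occupied lattice sites, together with its
#' voxel calibration and the physical position of the first voxel
#' center. All geometry downstream (meshes, centroids, distances) is in
#' micrometers; the center of voxel `(i, j, k)` (1-based R indexing)
#' lies at `origin_offset + (i-1, j-1, k-1) * voxel_size`.
#'
#' The occupied region is expected to be a single face-connected
#' component; real segmented cells can have marginal defects, so a
#' violation raises a warning rather than an error. The grid is padded
#' so that at least one empty voxel separates the cell from the grid
#' border (compiled kernels rely on that margin).
#'
#' @param occupancy Logical (or 0/1) array with 2 or 3 dimensions.
#' @param calibration A [calibration()] object with matching
#'   dimensionality.
#' @param origin_offset Physical coordinates (um) of the center of the
#'   first voxel. Defaults to the zero vector.
#' @return An object of class `voxdiv_mask` with elements `occupancy`,
#'   `calibration`, `origin_offset`.
#' @export
cell_mask <- function(occupancy, calibration, origin_offset = NULL) {
  if (is.null(dim(occupancy)) || !length(dim(occupancy)) %in% c(2, 3))
    stop("occupancy must be a 2D matrix or 3D array")
  occ <- array(as.logical(occupancy), dim(occupancy))
  if (anyNA(occ)) stop("occupancy contains NA")
  nd <- length(dim(occ))
  if (length(calibration$voxel_size) < nd)
    stop("calibration dimensionality does not match the occupancy grid")
  calibration$voxel_size <- calibration$voxel_size[seq_len(nd)]
  if (!any(occ)) stop("mask is empty: at least one occupied site required")
  if (is.null(origin_offset)) origin_offset <- rep(0, nd)
  if (length(origin_offset) != nd) stop("origin_offset length mismatch")

  m <- structure(list(occupancy = occ, calibration = calibration,
                      origin_offset = as.numeric(origin_offset)),
                 class = "voxdiv_mask")
  m <- pad_mask(m)
  ncomp <- cpp_count_components(storage_labels(m$occupancy), dim(m$occupancy), 1L)
  if (ncomp > 1)
    warning("occupied region has ", ncomp,
            " face-connected components (expected 1)")
  m
}

# integer 0/1 view of a logical grid for the C++ kernels
storage_labels <- function(occ) {
  x <- array(0L, dim(occ))
  x[occ] <- 1L
  x
}

# grow the grid so occupied sites are >= `margin` voxels from the border
pad_mask <- function(mask, margin = 1L) {
  occ <- mask$occupancy
  nd <- length(dim(occ))
  idx <- which(occ, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  need_lo <- pmax(0L, margin + 1L - lo)
  need_hi <- pmax(0L, margin - (dim(occ) - hi))
  if (all(need_lo == 0L) && all(need_hi == 0L)) return(mask)
  newdim <- dim(occ) + need_lo + need_hi
  out <- array(FALSE, newdim)
  if (nd == 3) {
    out[need_lo[1] + seq_len(dim(occ)[1]),
        need_lo[2] + seq_len(dim(occ)[2]),
        need_lo[3] + seq_len(dim(occ)[3])] <- occ
  } else {
    out[need_lo[1] + seq_len(dim(occ)[1]),
        need_lo[2] + seq_len(dim(occ)[2])] <- occ
  }
  mask$occupancy <- out
  mask$origin_offset <- mask$origin_offset -
    need_lo * mask$calibration$voxel_size
  mask
}

#' @export
print.voxdiv_mask <- function(x, ...) {
  nd <- length(dim(x$occupancy))
  cat(sprintf("cell mask: %s grid, %d occupied sites (%.3f um^%d)\n",
              paste(dim(x$occupancy), collapse = " x "),
              sum(x$occupancy),
              sum(x$occupancy) * voxel_volume(x$calibration), nd))
  print(x$calibration)
  invisible(x)
}

#' Number of occupied sites
#' @param mask A `voxdiv_mask`.
#' @export
site_count <- function(mask) sum(mask$occupancy)

#' Physical centroid of a mask (um)
#' @param mask A `voxdiv_mask`.
#' @return Numeric vector (length 2 or 3) of the mean occupied voxel
#'   center position, in micrometers.
#' @export
mask_centroid <- function(mask) {
  idx <- which(mask$occupancy, arr.ind = TRUE)
  grid_to_phys(colMeans(idx), mask)
}

# 1-based (possibly fractional) grid index -> physical coordinates
grid_to_phys <- function(gidx, mask) {
  mask$origin_offset + (as.numeric(gidx) - 1) * mask$calibration$voxel_size
}

#' Digitize a synthetic cell shape
#'
#' Generates calibrated binary masks of the reference shapes used to
#' validate the division model: a sphere, a half-sphere, a quarter
#' sphere, and a truncated sphere (a sphere with a planar cap removed,
#' mimicking the shape of the single-cell embryo proper sitting on the
#' suspensor). A site is occupied when its voxel *center* lies inside
#' the continuous shape, matching the binary-mask semantics of the
#' division model. The shape is centered in its grid with a 2-voxel
#' empty margin.
#'
#' The half-sphere keeps the `z >= center` half; the quarter sphere
#' additionally keeps `y >= center`; the truncated sphere removes a
#' bottom slab of thickness `truncation_fraction * 2 * radius` with a
#' cut plane normal to the z axis.
#'
#' @param kind One of `"sphere"`, `"half_sphere"`, `"quarter_sphere"`,
#'   `"truncated_sphere"`.
#' @param radius Sphere radius in micrometers.
#' @param calibration A cubic or anisotropic [calibration()].
#' @param truncation_fraction Fraction of the diameter removed by the
#'   planar cut (truncated sphere only). Default 0.25.
#' @return A `voxdiv_mask`.
#' @examples
#' m <- digitize_shape("sphere", radius = 10 * 0.35, calibration(0.35))
#' site_count(m)  # close to (4/3) * pi * 10^3
#' @export
digitize_shape <- function(kind = c("sphere", "half_sphere",
                                    "quarter_sphere", "truncated_sphere"),
                           radius, calibration,
                           truncation_fraction = 0.25) {
  kind <- match.arg(kind)
  vs <- calibration$voxel_size
  if (length(vs) != 3) stop("digitize_shape builds 3D masks; need a 3D calibration")
  if (radius < 3 * max(vs)) stop("shape too small to discretize")
  if (kind == "truncated_sphere" &&
      (truncation_fraction <= 0 || truncation_fraction >= 1))
    stop("truncation_fraction must be in (0, 1)")

  n <- ceiling(2 * radius / vs) + 5  # 2-voxel margin each side
  n <- n + (n %% 2 == 0)             # odd: center falls on a voxel center
  cx <- (n + 1) / 2                  # center in 1-based grid coords
  # cut shapes place their cut planes *between* voxel layers (half-voxel
  # shift) so no center sits exactly on a cut; the full sphere stays
  # centered on a voxel center
  if (kind %in% c("half_sphere", "quarter_sphere", "truncated_sphere"))
    cx[3] <- cx[3] + 0.5
  if (kind == "quarter_sphere") cx[2] <- cx[2] + 0.5
  ax <- (seq_len(n[1]) - cx[1]) * vs[1]
  ay <- (seq_len(n[2]) - cx[2]) * vs[2]
  az <- (seq_len(n[3]) - cx[3]) * vs[3]
  r2 <- outer(outer(ax^2, ay^2, `+`), az^2, `+`)
  # strictly inside, with a relative shave so centers lying exactly on
  # the continuous boundary are excluded regardless of rounding noise
  occ <- r2 < radius^2 * (1 - 1e-12)
  inz <- function(cond_z) {
    keep <- array(rep(cond_z, each = n[1] * n[2]), dim(occ))
    occ & keep
  }
  occ <- switch(kind,
    sphere = occ,
    half_sphere = inz(az >= 0),
    quarter_sphere = {
      keep_y <- array(rep(rep(ay >= 0, each = n[1]), times = n[3]), dim(occ))
      inz(az >= 0) & keep_y
    },
    truncated_sphere = inz(az >= -radius + truncation_fraction * 2 * radius))
  cell_mask(occ, calibration,
            origin_offset = -(cx - 1) * vs)
}

#' Digitize a 2D disk
#'
#' 2D analog of [digitize_shape()] for the planar division model: a
#' disk of given radius, occupied where pixel centers fall inside.
#'
#' @param radius Disk radius in micrometers.
#' @param calibration A 2D (or cubic) [calibration()].
#' @return A 2D `voxdiv_mask`.
#' @export
digitize_disk <- function(radius, calibration) {
  vs <- calibration$voxel_size[1:2]
  if (radius < 3 * max(vs)) stop("shape too small to discretize")
  n <- ceiling(2 * radius / vs) + 5
  cx <- (n + 1) / 2
  ax <- (seq_len(n[1]) - cx[1]) * vs[1]
  ay <- (seq_len(n[2]) - cx[2]) * vs[2]
  occ <- outer(ax^2, ay^2, `+`) < radius^2
  calibration$voxel_size <- vs
  cell_mask(occ, calibration, origin_offset = -(cx - 1) * vs)
}

#' Resample a mask to cubic voxels
#'
#' Confocal stacks are acquired anisotropically; the division model and
#' the morphometric estimators assume cubic voxels. The mask is
#' resampled onto a cubic grid whose side equals the *largest* input
#' edge (e.g. 0.17 x 0.17 x 0.35 um becomes cubic 0.35 um) by majority
#' vote over a 3 x 3 x 3 supersampling of each target voxel, which
#' preserves binary semantics (no interpolated gray levels) while
#' keeping the total physical volume within a few percent for shapes a
#' few voxels across or larger.
#'
#' @param mask A `voxdiv_mask`.
#' @return A cubic-calibration `voxdiv_mask`; the input is returned
#'   unchanged if already cubic.
#' @export
resample_to_cubic <- function(mask) {
  if (is_cubic(mask$calibration)) return(mask)
  vs <- mask$calibration$voxel_size
  nd <- length(vs)
  side <- max(vs)
  olddim <- dim(mask$occupancy)
  extent <- olddim * vs
  newdim <- pmax(1L, as.integer(round(extent / side)))
  # majority vote over 3 subsamples per axis: a target voxel is
  # occupied when more than half of its 3^nd subpoints fall in
  # occupied source voxels
  submaps <- lapply(seq_len(nd), function(d) {
    lapply(c(-1, 0, 1) / 3, function(o) {
      pos <- (seq_len(newdim[d]) - 0.5 + o) * side
      idx <- as.integer(ceiling(pos / vs[d]))
      idx[idx < 1 | idx > olddim[d]] <- NA
      idx
    })
  })
  votes <- array(0L, newdim)
  grid_occ <- mask$occupancy
  for (sx in 1:3) for (sy in 1:3) {
    if (nd == 3) {
      for (sz in 1:3) {
        ix <- submaps[[1]][[sx]]; iy <- submaps[[2]][[sy]]
        iz <- submaps[[3]][[sz]]
        ox <- ifelse(is.na(ix), FALSE, TRUE)
        sub <- array(FALSE, newdim)
        sub[ox, !is.na(iy), !is.na(iz)] <-
          grid_occ[ix[ox], iy[!is.na(iy)], iz[!is.na(iz)]]
        votes <- votes + sub
      }
    } else {
      ix <- submaps[[1]][[sx]]; iy <- submaps[[2]][[sy]]
      sub <- array(FALSE, newdim)
      sub[!is.na(ix), !is.na(iy)] <-
        grid_occ[ix[!is.na(ix)], iy[!is.na(iy)]]
      votes <- votes + sub
    }
  }
  occ <- votes > 3^nd / 2
  cal <- calibration(rep(side, nd))
  # keep the physical position of the first new voxel center consistent
  new_origin <- mask$origin_offset - vs / 2 + side / 2
  suppressWarnings(cell_mask(occ, cal, origin_offset = new_origin))
}
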