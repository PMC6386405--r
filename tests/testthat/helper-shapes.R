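# shared fixtures: small shapes and brute-force oracles

side_um <- 0.35

sphere_mask <- function(radius_vox, side = side_um) {
  digitize_shape("sphere", radius = radius_vox * side, calibration(side))
}

# brute-force count of lattice centers strictly inside a ball of radius
# r (in voxel units), independent of the digitizer under test
brute_ball_count <- function(r) {
  n <- ceiling(r) + 1
  ax <- -n:n
  sum(outer(outer(ax^2, ax^2, `+`), ax^2, `+`) < r^2)
}

# exhaustive discordant-pair enumeration on a labelled grid
# (26-neighborhood in 3D, 8 in 2D), counting unordered pairs once
brute_discordant_pairs <- function(labels) {
  dims <- dim(labels)
  nd <- length(dims)
  idx <- which(labels != 0, arr.ind = TRUE)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  count <- 0
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    for (k in seq_len(nrow(offs))) {
      q <- p + offs[k, ]
      if (any(q < 1) || any(q > dims)) next
      lq <- labels[matrix(q, 1)]
      if (lq != 0 && lq != labels[matrix(p, 1)]) count <- count + 1
    }
  }
  count / 2  # each unordered pair visited twice
}

# small solid box mask (3D)
box_mask <- function(nx, ny, nz, side = 1) {
  occ <- array(FALSE, c(nx + 4, ny + 4, nz + 4))
  occ[3:(nx + 2), 3:(ny + 2), 3:(nz + 2)] <- TRUE
  cell_mask(occ, calibration(side))
}

# a flat mid-plane partition of a mask along the z axis
flat_partition <- function(mask) {
  occ <- mask$occupancy
  idx <- which(occ, arr.ind = TRUE)
  zmid <- mean(range(idx[, 3]))
  lab <- array(0L, dim(occ))
  lab[occ] <- ifelse(which(occ, arr.ind = TRUE)[, 3] <= zmid, 1L, 2L)
  partition_from_labels(mask, lab)
}

tri_area_sum <- function(soup) {
  u <- soup[, 4:6, drop = FALSE] - soup[, 1:3, drop = FALSE]
  v <- soup[, 7:9, drop = FALSE] - soup[, 1:3, drop = FALSE]
  0.5 * sum(sqrt((u[, 2] * v[, 3] - u[, 3] * v[, 2])^2 +
                 (u[, 3] * v[, 1] - u[, 1] * v[, 3])^2 +
                 (u[, 1] * v[, 2] - u[, 2] * v[, 1])^2))
}
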