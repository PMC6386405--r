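test_that("calibration validates inputs and detects cubic grids", {
  expect_true(is_cubic(calibration(0.35)))
  expect_false(is_cubic(calibration(c(0.17, 0.17, 0.35))))
  expect_error(calibration(c(0.1, -0.2, 0.3)), "positive")
  expect_equal(voxel_volume(calibration(c(0.17, 0.17, 0.35))),
               0.17 * 0.17 * 0.35)
  expect_equal(voxel_diagonal(calibration(0.35)), sqrt(3) * 0.35)
})

test_that("digitized sphere counts match the brute-force lattice oracle", {
  for (r in c(5, 10)) {
    m <- sphere_mask(r)
    expect_equal(site_count(m), brute_ball_count(r))
  }
  # volume convergence at generic radii (no lattice points exactly on
  # the boundary, where the strict inside test is a measure-zero choice)
  for (r in c(5.3, 10.2)) {
    m <- sphere_mask(r)
    rel_err <- abs(site_count(m) - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3)
    expect_lt(rel_err, if (r >= 10) 0.02 else 0.05)
  }
})

test_that("half and quarter spheres are the right fractions of the sphere", {
  full <- site_count(sphere_mask(10))
  half <- site_count(digitize_shape("half_sphere", 10 * side_um,
                                    calibration(side_um)))
  quarter <- site_count(digitize_shape("quarter_sphere", 10 * side_um,
                                       calibration(side_um)))
  expect_gt(half / full, 0.48); expect_lt(half / full, 0.52)
  expect_gt(quarter / full, 0.23); expect_lt(quarter / full, 0.27)
})

test_that("truncated sphere removes the requested slab and tiny radii error", {
  tr <- digitize_shape("truncated_sphere", 10 * side_um,
                       calibration(side_um), truncation_fraction = 0.25)
  full <- sphere_mask(10)
  expect_lt(site_count(tr), site_count(full))
  # cap of depth 0.25 * diameter holds ~ 15.6% of the ball volume
  expected_frac <- 1 - (3 * 0.5^2 - 0.5^3) / 4  # spherical cap, h = R/2
  expect_equal(site_count(tr) / site_count(full), expected_frac,
               tolerance = 0.03)
  expect_error(digitize_shape("sphere", 2 * side_um, calibration(side_um)),
               "too small")
})

test_that("masks keep an empty margin and a connectivity warning fires", {
  occ <- array(TRUE, c(3, 3, 3))  # touches every border
  m <- cell_mask(occ, calibration(1))
  expect_true(all(dim(m$occupancy) >= 5))
  border_occupied <- any(m$occupancy[c(1, dim(m$occupancy)[1]), , ]) ||
    any(m$occupancy[, c(1, dim(m$occupancy)[2]), ]) ||
    any(m$occupancy[, , c(1, dim(m$occupancy)[3])])
  expect_false(border_occupied)
  # origin shifts so physical positions are unchanged
  expect_equal(m$origin_offset, c(-1, -1, -1))

  two <- array(FALSE, c(7, 7, 7))
  two[2, 2, 2] <- TRUE; two[6, 6, 6] <- TRUE
  expect_warning(cell_mask(two, calibration(1)), "components")
})

test_that("label stack write-then-read round trip is exact", {
  lab <- array(0L, c(9, 7, 5))
  lab[2:4, 2:4, 2:3] <- 1L
  lab[6:8, 4:6, 3:4] <- 2L
  path <- tempfile(fileext = ".tif")
  write_label_stack(lab, path, calibration(c(0.17, 0.17, 0.35)))
  masks <- read_label_stack(path)  # calibration from the sidecar JSON
  expect_named(masks, c("1", "2"))
  expect_equal(site_count(masks[["1"]]), sum(lab == 1L))
  expect_equal(site_count(masks[["2"]]), sum(lab == 2L))
  expect_equal(masks[["1"]]$calibration$voxel_size, c(0.17, 0.17, 0.35))
  rt <- voxdivide:::read_label_array(path)
  expect_identical(rt, lab)

  expect_error(read_label_stack(tempfile(fileext = ".tif")))
  zero <- array(0L, c(4, 4, 2))
  p0 <- tempfile(fileext = ".tif")
  write_label_stack(zero, p0, calibration(1))
  expect_warning(res <- read_label_stack(p0), "no nonzero")
  expect_length(res, 0)
})

test_that("resampling to cubic preserves physical volume", {
  occ <- array(FALSE, c(14, 14, 9))
  occ[3:12, 3:12, 3:7] <- TRUE  # 10 x 10 x 5 voxels
  m <- cell_mask(occ, calibration(c(0.17, 0.17, 0.35)))
  r <- resample_to_cubic(m)
  expect_true(is_cubic(r$calibration))
  expect_equal(r$calibration$voxel_size[1], 0.35)
  v_before <- site_count(m) * voxel_volume(m$calibration)
  v_after <- site_count(r) * voxel_volume(r$calibration)
  expect_lt(abs(v_after - v_before) / v_before, 0.05)
  # already-cubic input is returned unchanged
  expect_identical(resample_to_cubic(r), r)
})
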