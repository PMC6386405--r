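test_that("relative measure follows the strict-inequality definition", {
  expect_equal(relative_measure(0.5, 1:10)$value, 0)
  expect_equal(relative_measure(11, 1:10)$value, 1)
  expect_equal(relative_measure(2.5, c(1, 2, 3, 4))$value, 0.5)
  # ties do not count under the strict rule; midrank counts half
  expect_equal(relative_measure(2, c(1, 2, 3, 4))$value, 0.25)
  expect_equal(relative_measure(2, c(1, 2, 3, 4), ties = "midrank")$value,
               0.375)
  expect_equal(relative_measure(5, 7)$value, 0)  # |S| = 1 gives {0, 1}
  expect_equal(relative_measure(9, 7)$value, 1)
  expect_error(relative_measure(1, numeric(0)), "empty")
})

test_that("relative measure is invariant under increasing transforms", {
  set.seed(1)
  refs <- stats::rnorm(25)
  x <- stats::rnorm(10)
  for (f in list(function(v) v^3, function(v) exp(v),
                 function(v) 3 * v - 7)) {
    expect_equal(voxdivide:::relative_values(f(x), f(refs)),
                 voxdivide:::relative_values(x, refs))
  }
})

test_that("self-comparison relative measures are uniform under the null", {
  # candidate and references drawn from one distribution: the relative
  # measure must be uniform on [0, 1]
  # the reference set must be large enough that the shared-sample
  # dependence between candidates is negligible (the reference regime
  # uses hundreds of alternative simulations per cell)
  set.seed(99)
  ks_stats <- replicate(50, {
    refs <- stats::rlnorm(400)
    xs <- stats::rlnorm(30)
    vals <- voxdivide:::relative_values(xs, refs)
    suppressWarnings(stats::ks.test(vals, "punif")$statistic)
  })
  crit <- 1.358 / sqrt(30)  # 5% critical value, n = 30
  expect_gte(mean(ks_stats < crit), 0.9)
})

test_that("nested rule filters, minimizes and reports admissibility", {
  mk <- function(dist, area, d1 = 1, d2 = 1, seed = seq_along(dist)) {
    data.frame(seed = seed, area = area, anchor_distance = dist,
               n_components_d1 = d1, n_components_d2 = d2)
  }
  vox <- 1
  # single candidate close to the anchor is chosen
  r1 <- select_by_nested_rule(mk(0.2, 30), threshold = vox)
  expect_equal(r1$status, "ok"); expect_equal(r1$chosen_index, 1)

  # both admissible: least area governs even at larger distance
  r2 <- select_by_nested_rule(mk(c(0.5, 0.4), c(30, 40)), threshold = vox)
  expect_equal(r2$chosen_index, 1)
  expect_equal(r2$audit$status, c("chosen", "not_minimal"))

  # none within one voxel: explicit no-admissible result
  r3 <- select_by_nested_rule(mk(c(1.0, 2.4), c(5, 6)), threshold = vox)
  expect_equal(r3$status, "no_admissible_solution")
  expect_true(all(r3$audit$status == "too_far"))

  # fragmented candidates are excluded before the distance filter
  r4 <- select_by_nested_rule(mk(c(0.1, 0.2), c(5, 50), d1 = c(2, 1)),
                              threshold = vox)
  expect_equal(r4$chosen_index, 2)
  expect_equal(r4$audit$status[1], "fragmented")

  # ties: lower distance, then lower seed
  r5 <- select_by_nested_rule(mk(c(0.5, 0.3, 0.3), c(10, 10, 10),
                                 seed = c(3, 2, 9)), threshold = vox)
  expect_equal(r5$chosen_index, 2)

  # invariance to candidate order
  tab <- mk(c(0.9, 0.2, 0.6, 0.4), c(22, 18, 15, 40), seed = 1:4)
  perm <- c(3, 1, 4, 2)
  ra <- select_by_nested_rule(tab, threshold = vox)
  rb <- select_by_nested_rule(tab[perm, ], threshold = vox)
  expect_equal(ra$chosen$seed, rb$chosen$seed)
})

test_that("ensemble comparison computes per-regime relative measures", {
  conc <- data.frame(area = c(5, 12), anchor_distance = c(0.2, 0.6))
  regimes <- list(
    observed_rho = data.frame(area = c(6, 7, 8, 9),
                              anchor_distance = c(0.5, 1, 1.5, 2)),
    random_rho_centroid_constrained =
      data.frame(area = c(4, 6, 8), anchor_distance = c(0.1, 0.5, 3)))
  out <- ensemble_comparison(conc, regimes)
  o1 <- out[out$candidate == 1 & out$regime == "observed_rho", ]
  expect_equal(o1$relative_area, 0)       # smaller than all references
  expect_equal(o1$relative_distance, 0)
  c1 <- out[out$candidate == 1 &
              out$regime == "random_rho_centroid_constrained", ]
  expect_equal(c1$n_reference, 1)         # only the dist <= 0.2 reference
  expect_equal(c1$relative_area, 1)       # 5 > 4
  c2 <- out[out$candidate == 2 &
              out$regime == "random_rho_centroid_constrained", ]
  expect_equal(c2$n_reference, 2)
  expect_equal(c2$relative_area, 1)

  # empty constrained subset: skipped with a warning
  conc0 <- data.frame(area = 1, anchor_distance = 0.01)
  expect_warning(
    out0 <- ensemble_comparison(
      conc0, list(random_rho_centroid_constrained =
                    data.frame(area = 2, anchor_distance = 5))),
    "skipped")
  expect_null(out0)
})

test_that("plane classification thresholds angles in the embryo frame", {
  frame <- structure(list(origin = c(0, 0, 0),
                          i_axis = c(1, 0, 0), j_axis = c(0, -1, 0),
                          k_axis = c(0, 0, 1)), class = "voxdiv_frame")
  cellc <- c(2, 0, 0)  # radial direction = +x
  mk_meas <- function(n) data.frame(normal_x = n[1], normal_y = n[2],
                                    normal_z = n[3])
  expect_equal(classify_candidate(mk_meas(c(1, 0, 0)), frame, cellc)$class,
               "periclinal")
  expect_equal(classify_candidate(mk_meas(c(0, 0, 1)), frame, cellc)$class,
               "transverse")
  expect_equal(classify_candidate(mk_meas(c(0, 1, 0)), frame, cellc)$class,
               "anticlinal_longitudinal")
  # normal at > 30 degrees from every reference direction: other
  oblique <- c(1, 1, 1) / sqrt(3)  # 54.7 degrees from each axis
  expect_equal(classify_candidate(mk_meas(oblique), frame, cellc)$class,
               "other")
  expect_equal(classify_candidate(mk_meas(c(NA, NA, NA)), frame,
                                  cellc)$class, "other")
})
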