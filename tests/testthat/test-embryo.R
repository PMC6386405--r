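# a synthetic flat D1 mesh with normal along +x through the origin
flat_d1_mesh <- function() {
  m <- box_mask(8, 8, 8, side = 1)
  occ <- m$occupancy
  idx <- which(occ, arr.ind = TRUE)
  lab <- array(0L, dim(occ))
  lab[occ] <- ifelse(idx[, 1] <= mean(range(idx[, 1])), 1L, 2L)
  extract_interface_mesh(partition_from_labels(m, lab))
}

test_that("the embryo frame is built by projection as specified", {
  mesh <- flat_d1_mesh()
  g1 <- plane_summary(mesh, anchor = c(0, 0, 0))
  g1c <- c(g1$centroid_x, g1$centroid_y, g1$centroid_z)
  # suspensor below along -z with an i-axis component: k = projection
  # of G1->G2 onto the plane orthogonal to i, flipped to point apical
  g2 <- g1c + c(1, 0, -3)
  fr <- build_embryo_frame(mesh, g2)
  expect_equal(abs(fr$i_axis[1]), 1, tolerance = 1e-6)
  expect_equal(fr$k_axis, c(0, 0, 1), tolerance = 1e-6)  # away from G2
  # j = i x k exactly, orthonormal
  expect_equal(fr$j_axis,
               c(fr$i_axis[2] * fr$k_axis[3] - fr$i_axis[3] * fr$k_axis[2],
                 fr$i_axis[3] * fr$k_axis[1] - fr$i_axis[1] * fr$k_axis[3],
                 fr$i_axis[1] * fr$k_axis[2] - fr$i_axis[2] * fr$k_axis[1]),
               tolerance = 1e-9)
  gram <- rbind(fr$i_axis, fr$j_axis, fr$k_axis)
  expect_equal(gram %*% t(gram), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)

  # G2 - G1 already orthogonal to i: k is the (flipped) normalized vector
  fr2 <- build_embryo_frame(mesh, g1c + c(0, 0, -5))
  expect_equal(fr2$k_axis, c(0, 0, 1), tolerance = 1e-6)

  # G2 - G1 parallel to i: degenerate
  expect_error(build_embryo_frame(mesh, g1c + c(4, 0, 0)), "degenerate")
})

test_that("a small recursive simulation has exact binary structure", {
  m <- digitize_shape("truncated_sphere", 8 * side_um, calibration(side_um))
  tree <- simulate_embryogenesis(m, schedule = c(0.5, 0.5),
                                 n_runs_per_division = 6,
                                 params = model_params(n_cycles = 1200,
                                                       seed = 5))
  gens <- vapply(tree$nodes, function(n) n$generation, 1L)
  expect_equal(as.integer(table(gens)), c(1L, 2L, 4L))
  # children masks partition the parent exactly: site-disjoint, union
  for (nm in names(tree$nodes)) {
    node <- tree$nodes[[nm]]
    if (length(node$children) == 0) next
    k1 <- tree$nodes[[node$children[1]]]$mask
    k2 <- tree$nodes[[node$children[2]]]$mask
    expect_equal(site_count(k1) + site_count(k2), site_count(node$mask))
    expect_false(any(k1$occupancy & k2$occupancy))
    expect_identical(k1$occupancy | k2$occupancy, node$mask$occupancy)
    # the chosen plane satisfied the rule's distance bound (one
    # voxel diagonal)
    expect_lt(node$chosen$anchor_distance, sqrt(3) * side_um)
  }
  # newick topology mirrors the tree
  nw <- lineage_newick(tree)
  expect_match(nw, "^\\(.*\\)1_g1;$")
  expect_equal(lengths(regmatches(nw, gregexpr("g3", nw))), 4)
})

test_that("identical master seeds give identical lineage trees", {
  m <- digitize_shape("truncated_sphere", 7 * side_um, calibration(side_um))
  t1 <- simulate_embryogenesis(m, schedule = 0.5, n_runs_per_division = 4,
                               params = model_params(n_cycles = 800,
                                                     seed = 77))
  t2 <- simulate_embryogenesis(m, schedule = 0.5, n_runs_per_division = 4,
                               params = model_params(n_cycles = 800,
                                                     seed = 77))
  expect_identical(
    tree_labels <- lapply(t1$nodes, function(n) n$mask$occupancy),
    lapply(t2$nodes, function(n) n$mask$occupancy))
})

test_that("annotation splits 8C into apical/central and propagates", {
  # synthetic lineage: 8 cells in a 2 x 2 x 2 arrangement of boxes
  mk_box_at <- function(x0, y0, z0) {
    occ <- array(FALSE, c(14, 14, 14))
    occ[x0:(x0 + 3), y0:(y0 + 3), z0:(z0 + 3)] <- TRUE
    cell_mask(occ, calibration(1))
  }
  nodes <- list()
  nodes[["1"]] <- list(name = "1", generation = 1L, parent = NA,
                       children = c("1.1", "1.2"),
                       mask = mk_box_at(3, 3, 3))
  pos <- expand.grid(x = c(3, 8), y = c(3, 8), z = c(3, 8))
  # build intermediate generations with correct child links
  for (g in 2:3) {
    nms <- unlist(lapply(names(nodes)[vapply(nodes, function(n)
      n$generation, 1L) == g - 1], function(p) paste(p, 1:2, sep = ".")))
    for (nm in nms) {
      nodes[[nm]] <- list(name = nm, generation = g,
                          parent = sub("\\.[12]$", "", nm),
                          children = if (g < 3)
                            paste(nm, 1:2, sep = ".") else paste(nm, 1:2, sep = "."),
                          mask = mk_box_at(3, 3, 3))
    }
  }
  nms4 <- unlist(lapply(names(nodes)[vapply(nodes, function(n)
    n$generation, 1L) == 3], function(p) paste(p, 1:2, sep = ".")))
  for (i in seq_along(nms4)) {
    nodes[[nms4[i]]] <- list(name = nms4[i], generation = 4L,
                             parent = sub("\\.[12]$", "", nms4[i]),
                             children = character(),
                             mask = mk_box_at(pos$x[i], pos$y[i], pos$z[i]))
  }
  tree <- structure(list(nodes = nodes), class = "voxdiv_lineage")
  frame <- structure(list(origin = c(6.5, 6.5, 6.5),
                          i_axis = c(1, 0, 0), j_axis = c(0, -1, 0),
                          k_axis = c(0, 0, 1)), class = "voxdiv_frame")
  ann <- annotate_cells(tree, frame)
  doms <- vapply(nms4, function(nm) ann$nodes[[nm]]$annotation$domain, "")
  expect_equal(sum(doms == "apical"), 4)
  expect_equal(sum(doms == "central"), 4)
  # the four top boxes (z0 = 8) are apical
  expect_true(all(doms[pos$z == 8] == "apical"))

  # mirrored embryo: k -> -k swaps the annotation exactly
  frame_m <- frame; frame_m$k_axis <- -frame$k_axis
  ann_m <- annotate_cells(tree, frame_m)
  doms_m <- vapply(nms4, function(nm) ann_m$nodes[[nm]]$annotation$domain, "")
  expect_true(all((doms == "apical") == (doms_m == "central")))
})
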