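#' Embryo-centered coordinate frame
#'
#' Orthonormal frame used to annotate cells and classify plane
#' orientations: the origin is the centroid G1 of the first division
#' plane D1; `i` is the unit normal to D1; `k` is the normalized
#' projection of the vector from G1 to the suspensor centroid G2 onto
#' the D1 plane, sign-flipped so that `k` points away from the
#' suspensor (apical direction); and `j = i x k`.
#'
#' @param d1_mesh A `voxdiv_mesh` of the first division plane.
#' @param suspensor_centroid Physical point G2 (um): centroid of the
#'   last (uppermost) suspensor cell.
#' @return Object of class `voxdiv_frame`: list with `origin`,
#'   `i_axis`, `j_axis`, `k_axis`.
#' @export
build_embryo_frame <- function(d1_mesh, suspensor_centroid) {
  ps <- plane_summary(d1_mesh, anchor = suspensor_centroid)
  if (isTRUE(ps$degenerate_normal))
    stop("degenerate frame: D1 mesh has no well-defined normal")
  i <- c(ps$normal_x, ps$normal_y, ps$normal_z)
  g1 <- c(ps$centroid_x, ps$centroid_y, ps$centroid_z)
  g <- suspensor_centroid - g1
  k <- g - sum(g * i) * i
  nk <- sqrt(sum(k^2))
  if (nk < 1e-9 * max(sqrt(sum(g^2)), 1))
    stop("degenerate frame: G2 - G1 is parallel to the D1 normal")
  k <- -k / nk   # apical direction: away from the suspensor
  j <- c(i[2] * k[3] - i[3] * k[2],
         i[3] * k[1] - i[1] * k[3],
         i[1] * k[2] - i[2] * k[1])
  structure(list(origin = g1, i_axis = i, j_axis = j, k_axis = k),
            class = "voxdiv_frame")
}

#' @export
print.voxdiv_frame <- function(x, ...) {
  cat("embryo frame @ G1 =", paste(signif(x$origin, 4), collapse = ", "), "\n")
  for (ax in c("i_axis", "j_axis", "k_axis"))
    cat(" ", ax, "=", paste(signif(x[[ax]], 4), collapse = ", "), "\n")
  invisible(x)
}

#' Simulate embryogenesis by recursive application of the division rule
#'
#' Starting from an initial cell mask (canonically a truncated
#' sphere), simulates the successive rounds of division up to the
#' stage implied by the schedule: for every cell of every generation,
#' an ensemble of stochastic divisions is run at the scheduled target
#' ratio, the nested centroid-then-area rule selects the solution
#' passing within one voxel diagonal of the anchor with least
#' interface area, the mask is split along the chosen partition, and the
#' procedure recurses. If a cell yields no admissible solution its
#' ensemble is re-run once with twice as many runs; a second failure
#' aborts with a diagnostic naming the cell. There is no growth
#' between generations: daughters are used as-is.
#'
#' The default schedule reproduces the canonical 1C to 16C sequence:
#' symmetric divisions (0.5) for the first two rounds, then 0.45 and
#' 0.33.
#'
#' @param initial A 3D [cell_mask()].
#' @param schedule Numeric vector of per-transition target ratios;
#'   length = number of generations to simulate.
#' @param n_runs_per_division Ensemble size per cell (50 in the
#'   reference setting).
#' @param params Base [model_params()]; `seed` acts as the master
#'   seed of the whole simulation.
#' @param anchor_fun Function `(mask, cell_name) -> point` supplying
#'   the rule anchor per cell; defaults to the mask centroid. Supply
#'   nucleus centroids here to anchor the rule on nuclei instead.
#' @return An object of class `voxdiv_lineage`: list of `nodes`; each
#'   node has `name`, `generation` (1 = the initial cell), `parent`,
#'   `children`, `mask`, and for divided cells `chosen` (the selected
#'   candidate's measures row) and `ensemble_summary`. Node "1" is the
#'   root; children of node x are "x.1" (daughter 1) and "x.2".
#' @export
simulate_embryogenesis <- function(initial,
                                   schedule = c(0.5, 0.5, 0.45, 0.33),
                                   n_runs_per_division = 50,
                                   params = model_params(),
                                   anchor_fun = NULL) {
  stopifnot(length(schedule) >= 1, all(schedule > 0), all(schedule < 1))
  if (is.null(anchor_fun))
    anchor_fun <- function(mask, cell_name) mask_centroid(mask)
  # admissibility radius of the nested rule: one voxel diagonal, the
  # resolution limit of the discretized centroid-distance measurement
  # (the strongly asymmetric transitions select planes 1-2 voxel sides
  # from the centroid, as real measurements do)
  threshold <- voxel_diagonal(initial$calibration)
  nodes <- list(`1` = list(name = "1", generation = 1L, parent = NA_character_,
                           children = character(), mask = initial,
                           chosen = NULL))
  frontier <- "1"
  for (g in seq_along(schedule)) {
    nxt <- character()
    for (nm in frontier) {
      node <- nodes[[nm]]
      p <- params
      p$rho_star <- schedule[g]
      name_key <- sum(utf8ToInt(nm) * seq_along(utf8ToInt(nm)))
      p$seed <- derive_seed(params$seed, name_key * 131L + g)
      anchor <- anchor_fun(node$mask, nm)
      ens <- run_ensemble(node$mask, p, n_runs = n_runs_per_division,
                          rho_mode = "fixed", anchor = anchor)
      sel <- select_by_nested_rule(ens, threshold = threshold)
      if (sel$status != "ok") {
        p2 <- p
        p2$seed <- derive_seed(p$seed, 7777L)
        ens <- run_ensemble(node$mask, p2,
                            n_runs = 2L * n_runs_per_division,
                            rho_mode = "fixed", anchor = anchor)
        sel <- select_by_nested_rule(ens, threshold = threshold)
        if (sel$status != "ok")
          stop("no admissible division found for cell ", nm,
               " at generation ", g,
               " even after doubling the ensemble size")
      }
      part <- ens$partitions[[sel$chosen_index]]
      kids <- split_partition(part)
      child_names <- paste(nm, c(1, 2), sep = ".")
      node$children <- child_names
      node$chosen <- sel$chosen
      node$anchor <- anchor
      nodes[[nm]] <- node
      for (ci in 1:2) {
        nodes[[child_names[ci]]] <- list(
          name = child_names[ci], generation = g + 1L, parent = nm,
          children = character(), mask = kids[[ci]], chosen = NULL)
      }
      nxt <- c(nxt, child_names)
    }
    frontier <- nxt
  }
  structure(list(nodes = nodes, schedule = schedule,
                 master_seed = params$seed,
                 n_runs_per_division = n_runs_per_division),
            class = "voxdiv_lineage")
}

# split a mother mask into the two daughter masks along a partition;
# daughters keep the mother grid and calibration
split_partition <- function(partition) {
  m <- partition$mask
  lapply(1:2, function(l) {
    occ <- partition$labels == l
    suppressWarnings(cell_mask(occ, m$calibration,
                               origin_offset = m$origin_offset))
  })
}

#' @export
print.voxdiv_lineage <- function(x, ...) {
  gens <- vapply(x$nodes, function(n) n$generation, 1L)
  cat("lineage:", length(x$nodes), "cells;",
      paste(sprintf("%dC x %d", 2^(sort(unique(gens)) - 1),
                    tabulate(gens)[sort(unique(gens))]), collapse = ", "),
      "\n")
  invisible(x)
}

#' Cells of one generation
#' @param tree A `voxdiv_lineage`.
#' @param generation Generation index (1 = initial cell).
#' @return List of nodes.
#' @export
lineage_generation <- function(tree, generation) {
  Filter(function(n) n$generation == generation, tree$nodes)
}

#' Annotate lineage cells in the embryo frame
#'
#' Spatial annotation used to interpret simulated or reconstructed
#' embryos: at the 8-cell generation the four cells with larger
#' centroid projection on the `k` axis are labelled `apical`, the
#' others `central`; labels propagate to all descendants. At the
#' 16-cell generation each sister pair is additionally split into
#' `internal` (centroid projection closer to the first division
#' plane along `i`) and `external`.
#'
#' @param tree A `voxdiv_lineage` containing an 8-cell generation.
#' @param frame A `voxdiv_frame`.
#' @return The tree with `annotation` fields (`domain` and, where
#'   defined, `layer`) filled in.
#' @export
annotate_cells <- function(tree, frame) {
  gens <- vapply(tree$nodes, function(n) n$generation, 1L)
  if (!4L %in% gens) stop("8C generation absent from the lineage")
  names8 <- names(tree$nodes)[gens == 4L]
  kproj <- vapply(names8, function(nm)
    sum((mask_centroid(tree$nodes[[nm]]$mask) - frame$origin) *
          frame$k_axis), 0)
  srt <- sort(kproj, decreasing = TRUE)
  if (length(names8) >= 2) {
    gap <- srt[length(names8) / 2] - srt[length(names8) / 2 + 1]
    if (is.finite(gap) && abs(gap) < 1e-9)
      stop("ambiguous annotation: tied k-projections at the 8C stage")
  }
  apical <- names(srt)[seq_len(length(names8) / 2)]
  for (nm in names8) {
    dom <- if (nm %in% apical) "apical" else "central"
    tree <- propagate_domain(tree, nm, dom)
  }
  # internal/external within each 16C sister pair
  names16 <- names(tree$nodes)[gens == 5L]
  parents16 <- unique(vapply(names16, function(nm)
    tree$nodes[[nm]]$parent, ""))
  for (pn in parents16) {
    kids <- tree$nodes[[pn]]$children
    ip <- vapply(kids, function(nm)
      abs(sum((mask_centroid(tree$nodes[[nm]]$mask) - frame$origin) *
                frame$i_axis)), 0)
    if (abs(diff(ip)) < 1e-9)
      stop("ambiguous annotation: tied i-projections for sisters of ", pn)
    tree$nodes[[kids[which.min(ip)]]]$annotation$layer <- "internal"
    tree$nodes[[kids[which.max(ip)]]]$annotation$layer <- "external"
  }
  tree
}

propagate_domain <- function(tree, name, domain) {
  tree$nodes[[name]]$annotation$domain <- domain
  for (ch in tree$nodes[[name]]$children)
    tree <- propagate_domain(tree, ch, domain)
  tree
}

#' Newick export of the lineage topology
#'
#' Writes the division topology with generation tags as node labels,
#' for interoperability with tree viewers and `ape`.
#'
#' @param tree A `voxdiv_lineage`.
#' @return A single-line Newick string.
#' @export
lineage_newick <- function(tree) {
  rec <- function(nm) {
    node <- tree$nodes[[nm]]
    lab <- paste0(gsub("\\.", "_", nm), "_g", node$generation)
    if (length(node$children) == 0) return(lab)
    paste0("(", paste(vapply(node$children, rec, ""), collapse = ","),
           ")", lab)
  }
  paste0(rec("1"), ";")
}

#' Serialize a lineage to JSON
#'
#' Topology, generations, annotations and chosen-plane metrics (not
#' the voxel masks) in a machine-readable form.
#'
#' @param tree A `voxdiv_lineage`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lineage_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(n) {
    list(name = n$name, generation = n$generation,
         parent = n$parent, children = n$children,
         n_sites = site_count(n$mask),
         centroid = as.numeric(mask_centroid(n$mask)),
         annotation = n$annotation,
         chosen = if (!is.null(n$chosen)) as.list(n$chosen) else NULL)
  })
  jsonlite::write_json(
    list(master_seed = tree$master_seed, schedule = tree$schedule,
         n_runs_per_division = tree$n_runs_per_division,
         newick = lineage_newick(tree), nodes = unname(nodes)),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write per-generation label stacks of a lineage
#'
#' One TIFF per generation, in which every cell of that generation is
#' painted with its own integer label on the common grid; a JSON
#' sidecar maps labels to cell names.
#'
#' @param tree A `voxdiv_lineage`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_lineage_masks <- function(tree, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gens <- vapply(tree$nodes, function(n) n$generation, 1L)
  for (g in sort(unique(gens))) {
    cells <- names(tree$nodes)[gens == g]
    grid <- array(0L, dim(tree$nodes[[cells[1]]]$mask$occupancy))
    for (i in seq_along(cells))
      grid[tree$nodes[[cells[i]]]$mask$occupancy] <- i
    path <- file.path(dir, sprintf("generation_%02d.tif", g))
    write_label_stack(grid, path,
                      tree$nodes[[cells[1]]]$mask$calibration)
    jsonlite::write_json(as.list(stats::setNames(seq_along(cells), cells)),
                         file.path(dir, sprintf("generation_%02d_labels.json", g)),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
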