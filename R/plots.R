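#' Plot the energy trace of a division run
#'
#' Total, volume and interface energy per Monte-Carlo cycle; a quick
#' convergence diagnostic.
#'
#' @param division A `voxdiv_division` from [metropolis_division()].
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_energy_trace <- function(division) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tr <- division$trace
  long <- data.frame(
    cycle = rep(tr$cycle, 3),
    term = rep(c("H_V", "H_A", "H"), each = nrow(tr)),
    energy = c(tr$h_v, tr$h_a, tr$h_total))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cycle, y = .data$energy,
                                     color = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Monte-Carlo cycle", y = "energy [kT]",
                  color = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of ensemble plane measurements
#'
#' Distribution of one measured quantity (area, anchor distance,
#' realized ratio, ...) across an ensemble of simulated divisions.
#'
#' @param ensemble A `voxdiv_ensemble`.
#' @param what Column of the measures table to plot.
#' @param bins Histogram bin count.
#' @return A ggplot object.
#' @export
plot_ensemble <- function(ensemble, what = "area", bins = 20) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  df <- ensemble$measures
  stopifnot(what %in% names(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[what]])) +
    ggplot2::geom_histogram(bins = bins, fill = "grey40", color = "white") +
    ggplot2::labs(x = what, y = "count") +
    ggplot2::theme_minimal()
}
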