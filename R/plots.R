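type_palette <- function(n_t = 4) {
  pal <- c("lightblue", "green3", "orange", "red")
  if (n_t <= 4) pal[seq_len(n_t)] else grDevices::hcl.colors(n_t, "Zissou 1")
}

#' Plot the cell lattice
#'
#' Raster view of the label field coloured by cell type (light blue, green,
#' orange, red for types 1-4), with thin cell boundaries; the boundary ring
#' is blanked.
#'
#' @param object A `potts_system`.
#' @param show_boundaries Draw cell-cell boundaries.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(make_fixture("french_flag"))
#' @export
autoplot.potts_system <- function(object, show_boundaries = TRUE, ...) {
  lab <- object$labels
  W <- nrow(lab); H <- ncol(lab)
  df <- tibble::tibble(
    x = rep(seq_len(W), H), y = rep(seq_len(H), each = W),
    cell = as.vector(lab)
  )
  df$type <- ifelse(df$cell > 0, object$cells$type[pmax(df$cell, 1)],
                    NA_integer_)
  n_t <- object$params$n_t
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$type))) +
    ggplot2::scale_fill_manual(values = type_palette(n_t),
                               na.value = "grey30", name = "type",
                               breaks = seq_len(n_t)) +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
  if (show_boundaries) {
    edge <- df$cell > 0 & (
      df$cell != c(df$cell[-1], 0L) |
        df$cell != c(df$cell[-seq_len(W)], rep(0L, W)))
    p <- p + ggplot2::geom_point(data = df[edge, ], shape = ".",
                                 colour = "grey25", na.rm = TRUE)
  }
  p
}

#' @rdname autoplot.potts_system
#' @param sys A `potts_system`.
#' @export
plot_lattice <- function(sys, show_boundaries = TRUE) {
  autoplot.potts_system(sys, show_boundaries = show_boundaries)
}

#' Plot the cluster-count trace
#'
#' Cluster count against Monte Carlo time, with a dashed line at the number
#' of cell types (the correctly sorted state).
#'
#' @param object A `potts_trace`.
#' @param n_t Number of cell types.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potts_trace <- function(object, n_t = 4, ...) {
  ggplot2::ggplot(object$summary, ggplot2::aes(.data$mcs,
                                               .data$n_clusters)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = n_t, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "MCS", y = "number of clusters") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble summary
#'
#' Fractions of correct and stable runs per swept parameter value.
#'
#' @param object A `potts_ensemble`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.potts_ensemble <- function(object, ...) {
  s <- object$summary
  if (object$scenario$kind == "merging") {
    return(ggplot2::ggplot(s, ggplot2::aes(factor(.data$j),
                                           .data$mean_crossing)) +
      ggplot2::geom_col(fill = "steelblue") +
      ggplot2::labs(x = "j", y = "mean crossing time (MCS)") +
      ggplot2::theme_minimal())
  }
  sweep_var <- if (length(unique(s$mu0)) > 1) "mu0" else
    if (length(unique(s$j)) > 1) "j" else "eta"
  long <- tidyr::pivot_longer(s, c("f_correct", "f_stable"),
                              names_to = "metric", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data[[sweep_var]]),
                                     .data$fraction, fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(f_correct = "steelblue",
                                          f_stable = "indianred")) +
    ggplot2::labs(x = sweep_var, y = "fraction of runs") +
    ggplot2::theme_minimal()
}
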