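#' Plot activation patterns over the electrode grid
#'
#' Heat map of each pattern column reshaped onto the physical grid
#' (row-major channel order), one facet per component.
#'
#' @param d A `semg_decomposition` (or channels x components matrix).
#' @param grid A [grid_spec()] giving the layout.
#' @return A ggplot object.
#' @export
plot_activation_patterns <- function(d, grid = grid_spec()) {
  W <- if (inherits(d, "semg_decomposition")) d$patterns else d
  df <- purrr::map(seq_len(ncol(W)), function(k) {
    tibble::tibble(
      component = paste0("component ", k),
      row = rep(seq_len(grid$n_rows), each = grid$n_cols),
      col = rep(seq_len(grid$n_cols), times = grid$n_rows),
      weight = W[, k]
    )
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~component) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "grid column", y = "grid row", fill = "weight") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.semg_decomposition <- function(object, ...) {
  nt <- ncol(object$curves)
  df <- purrr::map(seq_len(nrow(object$curves)), function(k) {
    tibble::tibble(component = paste0("component ", k),
                   sample = seq_len(nt), value = object$curves[k, ])
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample, y = .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste0(toupper(object$method), " activation curves"),
                  x = "sample", y = "activation") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fos_model <- function(object, ...) {
  df <- tibble::tibble(step = seq_along(object$training_rmsd_path),
                       rmsd = object$training_rmsd_path,
                       term = object$selected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$rmsd)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$term), vjust = -0.8, size = 3) +
    ggplot2::labs(x = "basis functions in model", y = "training RMSD (%)") +
    ggplot2::theme_minimal()
}

#' Plot a method comparison
#'
#' Mean RMSD per method with +/- 1 SD error bars, from a
#' [compare_methods()] table.
#'
#' @param summary_tbl Output of [compare_methods()].
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(summary_tbl) {
  ggplot2::ggplot(summary_tbl,
                  ggplot2::aes(x = stats::reorder(.data$method, .data$mean_rmsd),
                               y = .data$mean_rmsd)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_rmsd - .data$sd_rmsd,
                                        ymax = .data$mean_rmsd + .data$sd_rmsd),
                           width = 0.2) +
    ggplot2::labs(x = "method", y = "RMSD (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
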