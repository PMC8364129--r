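#' Plot a chemical graph
#'
#' Tree layout with element labels on vertices and bond multiplicity shown
#' by line width.
#'
#' @param object a [chem_graph()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot chem_graph
#' @export
autoplot.chem_graph <- function(object, ...) {
  ig <- as_igraph(object)
  lay <- igraph::layout_as_tree(ig, root = match(find_center(object)[1], object$vertices$id))
  pos <- tibble::tibble(id = object$vertices$id, label = object$vertices$label,
                        x = lay[, 1], y = lay[, 2])
  seg <- dplyr::left_join(object$edges, pos, by = c("u" = "id")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(pos, by = c("v" = "id"), suffix = c("", ".v")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1,
                                       linewidth = factor(.data$m)),
                          colour = "grey40") +
    ggplot2::geom_point(data = pos, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 7, colour = "white") +
    ggplot2::geom_text(data = pos, ggplot2::aes(x = .data$x, y = .data$y,
                                                label = .data$label)) +
    ggplot2::scale_linewidth_manual(values = c(`1` = 0.5, `2` = 1.4, `3` = 2.4),
                                    name = "bond") +
    ggplot2::theme_void()
}

#' Plot cross-validation fold scores
#'
#' @param object a `cv_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$folds,
                  ggplot2::aes(x = factor(.data$fold), y = .data$r2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_r2, linetype = 2) +
    ggplot2::labs(x = "fold", y = expression(R^2),
                  title = "Cross-validated test R²") +
    ggplot2::theme_minimal()
}

#' Plot observed versus predicted property values
#'
#' @param model a `trained_predictor`.
#' @param dataset a [property_dataset()].
#' @return a ggplot object.
#' @export
plot_predictions <- function(model, dataset) {
  yhat <- predict(model, as.matrix(dataset$data[, dataset$spec$names]))
  df <- tibble::tibble(observed = dataset$data$value, predicted = yhat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "observed", y = "predicted") +
    ggplot2::theme_minimal()
}
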