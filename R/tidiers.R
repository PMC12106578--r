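#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fitted models and metric reports
#'
#' `tidy()` on a `cegcn_fit` returns the training curve (one row per epoch:
#' loss and validation MAP); on a `cegcn_metrics` it returns the per-query
#' table (age, query node, AP, reciprocal rank). `glance()` returns the
#' one-row summary in both cases.
#'
#' @param x A `cegcn_fit` or `cegcn_metrics` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cegcn_fit
#' @export
tidy.cegcn_fit <- function(x, ...) x$loss_curve

#' @rdname tidy.cegcn_fit
#' @method glance cegcn_fit
#' @export
glance.cegcn_fit <- function(x, ...) {
  tibble::tibble(
    model = if (x$config$evolve == "none") "static_gcn" else "cegcn",
    mode = x$mode,
    epochs_run = nrow(x$loss_curve),
    best_epoch = x$best_epoch,
    final_loss = x$loss_curve$loss[nrow(x$loss_curve)],
    best_val_map = suppressWarnings(max(x$loss_curve$val_map, na.rm = TRUE)),
    d = x$vocab$d,
    n_params = sum(vapply(x$params, length, numeric(1))),
    seed = x$config$seed
  )
}

#' @rdname tidy.cegcn_fit
#' @method tidy cegcn_metrics
#' @export
tidy.cegcn_metrics <- function(x, ...) x$queries

#' @rdname tidy.cegcn_fit
#' @method glance cegcn_metrics
#' @export
glance.cegcn_metrics <- function(x, ...) {
  tibble::tibble(map = x$map, mrr = x$mrr, n_queries = nrow(x$queries),
                 n_target_ages = length(x$ages), mode = x$mode,
                 block = x$block)
}

#' Plot methods
#'
#' `autoplot()` on a `cegcn_fit` draws the training loss and validation MAP
#' by epoch; on a `cegcn_metrics` the per-query AP by target age; on a
#' `snapshot_sequence` the edge count of the multimorbidity network by age.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cegcn_fit
#' @export
autoplot.cegcn_fit <- function(object, ...) {
  df <- object$loss_curve |>
    tidyr::pivot_longer(c("loss", "val_map"), names_to = "series") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "epoch", y = NULL, title = "Training curve")
}

#' @rdname autoplot.cegcn_fit
#' @method autoplot cegcn_metrics
#' @export
autoplot.cegcn_metrics <- function(object, ...) {
  ggplot2::ggplot(object$queries,
                  ggplot2::aes(factor(.data$age + 1), .data$ap)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.5) +
    ggplot2::labs(x = "target age", y = "average precision",
                  title = sprintf("Per-query AP (%s block, MAP = %.3f)",
                                  object$block, object$map))
}

#' @rdname autoplot.cegcn_fit
#' @method autoplot snapshot_sequence
#' @export
autoplot.snapshot_sequence <- function(object, ...) {
  ggplot2::ggplot(edge_summary(object),
                  ggplot2::aes(.data$age, .data$n_edges)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "edges",
                  title = sprintf("Multimorbidity network growth (%s mode)",
                                  object$mode))
}
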