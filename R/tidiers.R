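# broom-style tidiers and ggplot2 autoplot methods for fitted models and
# fold reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted model's training history
#'
#' @param x A `dragnet_model`.
#' @param ... Unused.
#' @return A long tibble with `epoch`, `quantity`
#'   (`loss`/`l1`/`l2`/`val_auc`/`val_aupr`) and `value`.
#' @export
tidy.dragnet_model <- function(x, ...) {
  tidyr::pivot_longer(x$history, -"epoch", names_to = "quantity",
                      values_to = "value")
}

#' One-row summary of a fitted model
#'
#' @param x A `dragnet_model`.
#' @param ... Unused.
#' @return A one-row tibble: epochs run, best epoch, best validation
#'   AUC/AUPR, final training loss, parameter count.
#' @export
glance.dragnet_model <- function(x, ...) {
  h <- x$history
  n_par <- sum(vapply(.collect_params(x$pn), function(p) length(p$v), 0))
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    val_auc = h$val_auc[x$best_epoch],
    val_aupr = h$val_aupr[x$best_epoch],
    final_loss = h$loss[nrow(h)],
    n_parameters = n_par
  )
}

#' Tidy a cross-validation fold report
#'
#' @param x A `fold_report`.
#' @param ... Unused.
#' @return A long tibble with `fold`, `metric`, `value`.
#' @export
tidy.fold_report <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), -dplyr::any_of(c("n", "prevalence"))),
    -"fold", names_to = "metric", values_to = "value")
}

#' Fold-aggregate summary of a cross-validation report
#'
#' @param x A `fold_report`.
#' @param ... Unused.
#' @return The mean/sd/se tibble from [summarize_folds()].
#' @export
glance.fold_report <- function(x, ...) {
  attr(x, "summary") %||% summarize_folds(x)
}

#' Plot training curves of a fitted model
#'
#' @param object A `dragnet_model`.
#' @param ... Unused.
#' @return A ggplot: losses and validation metrics over epochs.
#' @export
autoplot.dragnet_model <- function(object, ...) {
  df <- tidy.dragnet_model(object)
  df$panel <- ifelse(df$quantity %in% c("loss", "l1", "l2"),
                     "loss", "validation")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold metrics of a cross-validation report
#'
#' @param object A `fold_report`.
#' @param ... Unused.
#' @return A ggplot: one point per fold and metric with the fold mean.
#' @export
autoplot.fold_report <- function(object, ...) {
  df <- tidy.fold_report(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0)) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = "value", colour = "fold") +
    ggplot2::theme_minimal()
}
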