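#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a leave-one-out evaluation
#'
#' @param x A `dit_eval`.
#' @param ... Unused.
#' @return Long tibble of metric name/value pairs.
#' @method tidy dit_eval
#' @export
tidy.dit_eval <- function(x, ...) {
  x$metrics |>
    dplyr::select("sensitivity", "specificity", "accuracy", "youden",
                  "auc_balanced") |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "metric", values_to = "value")
}

#' One-row summary of a leave-one-out evaluation
#'
#' @param x A `dit_eval`.
#' @param ... Unused.
#' @return One-row tibble: configuration, metrics, confusion counts and
#'   number of selected features.
#' @method glance dit_eval
#' @export
glance.dit_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, m = x$m, formulation = x$formulation),
    x$metrics,
    tibble::tibble(n_selected = length(x$selected))
  )
}

#' Tidy a pipeline run
#'
#' @param x A `dit_run`.
#' @param ... Unused.
#' @return The per-configuration summary tibble.
#' @method tidy dit_run
#' @export
tidy.dit_run <- function(x, ...) x$summary

#' Plot phase-1 feature trajectories by class
#'
#' One panel per feature, one line per breast, colored by label — the
#' standard view of how recovery trajectories separate sick from healthy
#' breasts.
#'
#' @param features_tbl Long tibble from [extract_cohort_features()].
#' @param features Which features to panel (default: Average Temperature).
#' @return A ggplot object.
#' @export
plot_feature_series <- function(features_tbl,
                                features = "Average Temperature") {
  dat <- dplyr::filter(features_tbl, .data$feature %in% features)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$step, y = .data$value,
    group = .data$breast_id, colour = .data$label
  )) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(healthy = "#2166ac", sick = "#b2182b")) +
    ggplot2::labs(x = "frame / pair index", y = "feature value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot dit_eval
#' @export
autoplot.dit_eval <- function(object, ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(
      x = NULL, y = "value",
      title = sprintf("%s, k=%s m=%s", object$formulation, object$k, object$m)
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot dit_run
#' @export
autoplot.dit_run <- function(object, ...) {
  dat <- dplyr::mutate(object$summary,
                       config = sprintf("k=%d m=%d", .data$k, .data$m))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$config, .data$k * 10 + .data$m),
    y = .data$accuracy
  )) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "sub-series configuration", y = "LOOCV accuracy (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
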