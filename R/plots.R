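#' Plot a Kaplan-Meier curve
#'
#' Step plot of the product-limit estimate from [km_estimate()].
#'
#' @param object a `km_fit`.
#' @param ... unused.
#'
#' @return A ggplot object.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    tibble::as_tibble(object)[c("time", "survival")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Follow-up (months)", y = "Survival probability") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a group-comparison DE scan
#'
#' Mean fold change (log2) against -log10 q from [smoke_response_de()],
#' with the over/under calls highlighted.
#'
#' @param de a [smoke_response_de()] result.
#' @param cfg the [analysis_config()] used, for the threshold guides.
#'
#' @return A ggplot object.
#' @export
plot_volcano <- function(de, cfg = analysis_config()) {
  ggplot2::ggplot(de, ggplot2::aes(x = log2(.data$mean_fold),
                                   y = -log10(.data$q),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_vline(xintercept = log2(c(cfg$fc_under, cfg$fc_over)),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(cfg$q_threshold),
                        linetype = "dashed", colour = "grey50") +
    ggplot2::scale_colour_manual(
      values = c(over = "#c0392b", under = "#2980b9", none = "grey70")
    ) +
    ggplot2::labs(x = "log2 mean fold change", y = "-log10 q",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Bar chart of smoking-status specificity patterns
#'
#' Counts of [classify_specificity()] patterns split by direction.
#'
#' @param spec_calls a [classify_specificity()] result.
#'
#' @return A ggplot object.
#' @export
plot_specificity <- function(spec_calls) {
  counts <- spec_calls |>
    dplyr::count(.data$pattern, .data$direction)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pattern, y = .data$n,
                                       fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "miRNAs", fill = "direction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Degree distribution of a target network
#'
#' @param object a `target_network` from [build_network()].
#' @param ... unused.
#'
#' @return A ggplot object.
#' @method autoplot target_network
#' @export
autoplot.target_network <- function(object, ...) {
  df <- dplyr::bind_rows(
    object$mirnas |> dplyr::transmute(degree = .data$degree, type = "miRNA"),
    object$genes |> dplyr::transmute(degree = .data$degree, type = "gene")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, fill = .data$type)) +
    ggplot2::geom_histogram(bins = 30, position = "identity", alpha = 0.6) +
    ggplot2::labs(x = "Node degree", y = "Nodes", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
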