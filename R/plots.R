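#' Correlation heatmap
#'
#' @param object An `lxt_cormat` from [correlate_traits()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lxt_cormat <- function(object, ...) {
  df <- tidy.lxt_cormat(object)
  df <- dplyr::bind_rows(
    df,
    dplyr::rename(df, trait1 = "trait2", trait2 = "trait1"),
    tibble(trait1 = rownames(object$r), trait2 = rownames(object$r),
           r = 1, p_value = 0, n = NA_integer_, signif = "")
  )
  lv <- rownames(object$r)
  df$trait1 <- factor(df$trait1, levels = lv)
  df$trait2 <- factor(df$trait2, levels = rev(lv))
  ggplot2::ggplot(df, ggplot2::aes(.data$trait1, .data$trait2,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$trait1 == .data$trait2, "",
                     paste0(sprintf("%.2f", .data$r), .data$signif))
    ), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal()
}

#' Observed versus GCA-predicted hybrid performance
#'
#' @param object An `lxt_cv` from [loo_gca_cv()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lxt_cv <- function(object, ...) {
  df <- dplyr::filter(object$predictions, !is.na(.data$predicted))
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = 2) +
    ggplot2::labs(
      x = "GCA-predicted performance", y = "Observed performance",
      subtitle = sprintf("r(GCA, TCP) = %.2f, n = %d", object$r,
                         object$n_predicted)
    ) +
    ggplot2::theme_minimal()
}

#' Distribution of GCA effects
#'
#' @param object An `lxt_ca` from [estimate_gca_sca()].
#' @param ... Unused.
#' @return A ggplot of line GCA effects ranked by size.
#' @export
autoplot.lxt_ca <- function(object, ...) {
  df <- dplyr::arrange(object$gca_line, .data$effect)
  df$line_id <- factor(df$line_id, levels = df$line_id)
  ggplot2::ggplot(df, ggplot2::aes(.data$line_id, .data$effect)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "Line", y = "GCA effect") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Trait distributions by management regime
#'
#' Histograms of plot-level trait values, split by regime when two regimes
#' are present.
#'
#' @param data A plot table.
#' @param traits Trait columns to show; defaults to the standard six.
#' @param bins Number of histogram bins.
#' @return A ggplot.
#' @export
plot_trait_distributions <- function(data, traits = NULL, bins = 40) {
  data <- as_tibble(data)
  if (is.null(traits)) {
    traits <- intersect(c("GY", "AD", "SD", "ASI", "PH", "EH"), names(data))
  }
  long <- tidyr::pivot_longer(
    data[, c(intersect("regime", names(data)), traits)],
    dplyr::all_of(traits), names_to = "trait"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
    ggplot2::facet_wrap(~trait, scales = "free") +
    ggplot2::labs(x = NULL, y = "Plots") +
    ggplot2::theme_minimal()
  if ("regime" %in% names(long)) {
    p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data$regime), bins = bins, alpha = 0.6,
      position = "identity"
    )
  } else {
    p + ggplot2::geom_histogram(bins = bins)
  }
}
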