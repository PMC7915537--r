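#' Plot an extracted ion chromatogram
#'
#' @param object An `eic_trace` from [extract_eic()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.eic_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rt_min,
                                       y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Retention time (min)", y = "Intensity (counts)",
      title = sprintf("EIC m/z %.4f (%g mDa window)",
                      attr(object, "target_mz"), attr(object, "window_mda"))
    )
}

#' Plot a melting fit
#'
#' Observed birefringence points with the fitted two-transition Hill curve.
#'
#' @param object A `melt_fit` from [fit_melting()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.melt_fit <- function(object, ...) {
  curve <- object$curve
  grid <- tibble::tibble(
    temperature_K = seq(min(curve$temperature_K), max(curve$temperature_K),
                        length.out = 400)
  )
  grid$birefringence <- hill_model(grid$temperature_K, object$params)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$temperature_K,
                                      y = .data$birefringence)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "Temperature (K)", y = "Birefringence (normalized)",
                  title = sprintf("T1 = %.1f K, T2 = %.1f K, r² = %.4f",
                                  object$params$T1, object$params$T2,
                                  object$r_squared))
}

#' Bar plot of a CE chain-length profile
#'
#' @param profile Output of [chain_profile()].
#' @return A ggplot object.
#' @export
plot_chain_profile <- function(profile) {
  profile$label <- stats::reorder(profile$label, profile$label_id)
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$label,
                                        y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Share of CE signal (%)") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1))
}

#' Bar plot of the lipid class balance
#'
#' @param balance Output of [class_balance()].
#' @return A ggplot object.
#' @export
plot_class_balance <- function(balance) {
  balance$lipid_class <- factor(balance$lipid_class,
                                levels = c("Chl", "CE", "WE", "TAG"))
  ggplot2::ggplot(balance, ggplot2::aes(x = .data$lipid_class,
                                        y = .data$percent)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Share of total (%)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
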