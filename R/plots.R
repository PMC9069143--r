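#' Plot conspicuity against b-value
#'
#' SIR and CNR_eff of LTE-DWI and STE-DWI as a function of b-value; the
#' synthetic counterpart of the per-patient b-sweep panels.
#'
#' @param object a `"conspicuity_curves"` tibble from [conspicuity_vs_b()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.conspicuity_curves <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
    cols = c("sir", "cnr_eff"),
    names_to = "quantity", values_to = "value"
  )
  long$quantity <- factor(long$quantity,
    levels = c("sir", "cnr_eff"),
    labels = c("SIR", "CNR[eff]")
  )
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$b_value, y = .data$value,
    colour = .data$modality, linetype = .data$modality
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity,
      scales = "free_y",
      labeller = ggplot2::label_parsed
    ) +
    ggplot2::labs(
      x = expression(italic(b) ~ (s / mm^2)), y = NULL,
      colour = "Encoding", linetype = "Encoding"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a phantom label slice
#'
#' Mid-axial slice of the tissue label volume.
#'
#' @param object a `"digital_phantom"`.
#' @param slice axial slice index (default: middle).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.digital_phantom <- function(object, slice = NULL, ...) {
  g <- dim(object$labels)
  slice <- slice %||% ceiling(g[3] / 2)
  df <- expand.grid(x = seq_len(g[1]), y = seq_len(g[2]))
  df$tissue <- factor(
    object$labels[cbind(df$x, df$y, slice)],
    levels = 0:length(object$label_names),
    labels = c("background", object$label_names)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$tissue)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Phantom labels, slice %d", slice)) +
    ggplot2::theme_minimal()
}

#' Plot a modality image slice
#'
#' @param object a `"modality_image"` from [directional_average()].
#' @param slice axial slice index (default: middle).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.modality_image <- function(object, slice = NULL, ...) {
  g <- dim(object$values)
  slice <- slice %||% ceiling(g[3] / 2)
  df <- expand.grid(x = seq_len(g[1]), y = seq_len(g[2]))
  df$signal <- object$values[cbind(df$x, df$y, slice)]
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$signal)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf(
      "%s-DWI, b = %g s/mm%s, slice %d",
      object$modality, object$b_value, "²", slice
    )) +
    ggplot2::theme_minimal()
}
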