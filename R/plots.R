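#' Plot normalized volume trends against the reference curve
#'
#' @param template_curves data.frame with columns `age`, `roi`, `vnorm`
#'   (e.g. from [template_volumes()] piped through [normalized_volumes()]).
#' @param reference data.frame from [binned_reference_volumes()] (optional).
#' @return a ggplot object.
#' @export
plot_volume_trends <- function(template_curves, reference = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- ggplot2::ggplot(template_curves,
                       ggplot2::aes(x = .data$age, y = .data$vnorm)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::geom_point(color = "#2c7fb8", size = 1) +
    ggplot2::facet_wrap(~roi, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = "normalized volume",
                  title = "Conditional-template volume trends") +
    ggplot2::theme_minimal()
  if (!is.null(reference)) {
    ref <- reference[is.finite(reference$vnorm), ]
    p <- p +
      ggplot2::geom_ribbon(data = ref,
                           ggplot2::aes(x = .data$bin_centre, y = .data$vnorm,
                                        ymin = .data$ci_lo, ymax = .data$ci_hi),
                           alpha = 0.2, fill = "grey40") +
      ggplot2::geom_line(data = ref,
                         ggplot2::aes(x = .data$bin_centre, y = .data$vnorm),
                         color = "grey30", linetype = 2)
  }
  p
}

#' Plot the pooled Jacobian-determinant distribution
#'
#' @param report output of [jacobian_report()].
#' @return a ggplot object.
#' @export
plot_jacobian_distribution <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  h <- report$histogram
  df <- data.frame(mid = h$mids, count = h$counts)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(fill = "#2c7fb8", width = diff(h$breaks)[1]) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Jacobian determinant", y = "voxels",
                  title = "Deformation Jacobian determinants") +
    ggplot2::theme_minimal()
}

#' Plot the training loss trace
#'
#' @param ckpt checkpoint from [run_training()].
#' @param components which loss columns to show.
#' @return a ggplot object.
#' @export
plot_loss_trace <- function(ckpt, components = c("total", "recon", "mean")) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  log <- ckpt$loss_log
  df <- do.call(rbind, lapply(components, function(cn)
    data.frame(epoch = log$epoch, component = cn, value = log[[cn]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value,
                                   color = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss", title = "Training losses") +
    ggplot2::theme_minimal()
}
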