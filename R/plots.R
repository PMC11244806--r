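# ggplot2 helpers for the tabular result types. ggplot2 is a suggested
# dependency; the functions error informatively when it is missing.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting needs the 'ggplot2' package")
  }
}

#' Plot a depth-intensity profile
#'
#' Mean slice intensity against depth, the readout contrasting
#' experimentally attenuated channels with virtual predictions.
#'
#' @param ... One or more `tg_depth_profile` data frames (overlaid by
#'   channel).
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(...) {
  need_ggplot()
  df <- do.call(rbind, list(...))
  ggplot2::ggplot(df, ggplot2::aes(x = z_um, y = mean_intensity,
                                   colour = channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "depth (µm)", y = "mean intensity",
                  colour = "channel") +
    ggplot2::theme_minimal()
}

#' Box plots of a cube-wise metric report
#'
#' One box per metric: median line, quartile box, whiskers spanning the
#' full data range.
#'
#' @param report A `tg_metric_report`.
#' @param metrics Metric columns to show (default: all).
#' @return A ggplot object.
#' @export
plot_metric_report <- function(report, metrics = NULL) {
  need_ggplot()
  cols <- setdiff(names(report), c("cube", "z0", "y0", "x0"))
  if (!is.null(metrics)) cols <- intersect(cols, metrics)
  long <- do.call(rbind, lapply(cols, function(m) {
    data.frame(metric = m, value = report[[m]])
  }))
  long <- long[is.finite(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(x = metric, y = value)) +
    ggplot2::geom_boxplot(coef = Inf) +  # whiskers at the data range
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = NULL)
}

#' Plot an axis profile with error bars
#'
#' Per-bin mean with standard-deviation error bars along the normalized
#' lobule (CV-PV) coordinate.
#'
#' @param profile A `tg_axis_profile`.
#' @param ylab Axis label for the quantity.
#' @return A ggplot object.
#' @export
plot_axis_profile <- function(profile, ylab = "value") {
  need_ggplot()
  df <- profile[profile$n > 0, ]
  ggplot2::ggplot(df, ggplot2::aes(x = bin_center, y = mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean - sd,
                                        ymax = mean + sd),
                           width = 0.02, na.rm = TRUE) +
    ggplot2::labs(x = "normalized CV→PV position", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Generator/discriminator (or train/validation) loss traces per epoch.
#'
#' @param history The `history` data frame of a fitted model.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  need_ggplot()
  cols <- intersect(c("total_G", "total_D", "train_loss", "val_loss"),
                    names(history))
  long <- do.call(rbind, lapply(cols, function(m) {
    data.frame(epoch = history$epoch, loss = history[[m]], term = m)
  }))
  long <- long[is.finite(long$loss), ]
  ggplot2::ggplot(long, ggplot2::aes(x = epoch, y = loss,
                                     colour = term)) +
    ggplot2::geom_line() +
    ggplot2::theme_minimal()
}
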