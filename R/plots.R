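# Plotting: base-graphics radiograph display plus ggplot2 autoplot methods
# for reports (ggplot2 is suggested, not required).

#' Display a radiograph
#'
#' Grayscale display with image row 1 (superior) at the top. Difference
#' images (`pibs_image` with possible negative values) are shown with a
#' symmetric window about 0.
#'
#' @param x a [radiograph()] or `pibs_image`.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.radiograph <- function(x, main = NULL, ...) {
  v <- x$values
  if (inherits(x, "pibs_image")) {
    w <- max(abs(range(v)))
    zlim <- c(-w, w)
  } else zlim <- range(v)
  if (is.null(main))
    main <- sprintf("%s, gantry %.0f deg", x$domain, x$geometry$gantry_deg)
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], zlim = zlim,
                  col = grDevices::gray.colors(256, 0, 1), axes = FALSE,
                  asp = nrow(v) / ncol(v), main = main, ...)
  invisible(x)
}

#' @export
plot.pibs_image <- plot.radiograph

#' Per-angle CNR comparison plot
#'
#' Line plot of the mean PIBS and conventional CNR against gantry angle.
#'
#' @param object a `pibs_report` from [evaluation_report()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pibs_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot")
  d <- object$contrast
  agg <- stats::aggregate(cnr ~ angle_deg + kind, data = d, FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = angle_deg, y = cnr,
                                    colour = kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gantry angle (deg)", y = "tumor CNR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Motion-trace plot
#'
#' Recovered versus true superior/inferior tumor displacement per
#' respiratory state.
#'
#' @param object a `motion_trace` from [track_motion()].
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.motion_trace <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for autoplot")
  ggplot2::ggplot(object, ggplot2::aes(x = state)) +
    ggplot2::geom_line(ggplot2::aes(y = truth_mm), linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(y = displacement_mm,
                                     shape = low_confidence), size = 3) +
    ggplot2::labs(x = "respiratory state", y = "SI displacement (mm)",
                  shape = "low confidence") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("angle_deg", "cnr", "kind", "state",
                         "truth_mm", "displacement_mm", "low_confidence"))
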