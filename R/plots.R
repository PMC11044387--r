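# ggplot2 displays mirroring the conventional SSC figure axes: segmental
# rotation on y, cumulative C4-C7 rotation on x.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an SSC curve
#'
#' Segmental contribution (degrees per frame) against cumulative C4-C7
#' rotation, one line per motion segment, optionally marking the detected
#' significant peaks.
#'
#' @param object An `ssc_curve`.
#' @param mark_peaks Mark significant peaks (default `TRUE`).
#' @param config [classifier_config()] used for peak marking.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ssc_curve <- function(object, mark_peaks = TRUE,
                               config = classifier_config(), ...) {
  if (attr(object, "insufficient_motion")) {
    abort("cannot plot: recording flagged as insufficient motion.")
  }
  p <- ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$x, y = .data$contribution_per_frame,
                 colour = .data$segment)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "cumulative C4-C7 rotation (deg)",
      y = "segmental rotation (deg/frame)",
      colour = "segment"
    ) +
    ggplot2::theme_minimal()
  if (mark_peaks) {
    pk <- detect_peaks(object, config)
    pk <- pk[pk$significant, , drop = FALSE]
    if (nrow(pk) > 0) {
      p <- p + ggplot2::geom_point(
        data = pk,
        ggplot2::aes(x = .data$x, y = .data$height, colour = .data$segment),
        shape = 17, size = 2.5
      )
    }
  }
  p
}

#' Plot the segmental angle series of a recording
#'
#' @param object A `gt_recording`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gt_recording <- function(object, ...) {
  ggplot2::ggplot(
    object$angles,
    ggplot2::aes(x = .data$frame, y = .data$angle_deg,
                 colour = .data$segment)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "segmental angle (deg)",
                  colour = "segment") +
    ggplot2::theme_minimal()
}
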