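#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a normative band
#'
#' Draws the predicted normative function with its plus/minus k-SD envelope
#' (dashed), optionally overlaying observed cohort values.
#'
#' @param object An `sr2_band` from [normative_band()].
#' @param cohort Optional cohort table; observed values of the band's
#'   measure are overplotted as open circles.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot sr2_band
#' @export
autoplot.sr2_band <- function(object, cohort = NULL, ...) {
  vary <- attr(object, "vary")
  model <- attr(object, "model")
  xlab <- if (vary == "age") "Age (years)" else "Standard PTA (dB HL)"
  ylab <- if (model$condition == "srm") "SRM (dB)" else
    sprintf("%s threshold (dB TMR)",
            sub("^(\\w)", "\\U\\1", model$condition, perl = TRUE))
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data[[vary]])) +
    ggplot2::geom_line(ggplot2::aes(y = .data$center)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
  if (!is.null(cohort)) {
    measure <- measure_label(model$condition, model$run)
    xcol <- if (vary == "age") "age" else "pta_st"
    if (all(c(measure, xcol) %in% names(cohort))) {
      pts <- tibble::tibble(x = cohort[[xcol]], y = cohort[[measure]])
      p <- p + ggplot2::geom_point(data = pts,
                                   ggplot2::aes(x = .data$x, y = .data$y),
                                   shape = 1)
    }
  }
  p
}

#' Plot per-participant Z-scores by measure
#'
#' @param report A long Z-score report from [z_report()].
#' @param k Flagging criterion drawn as horizontal reference lines.
#' @return A ggplot.
#' @export
plot_z_report <- function(report, k = 2) {
  report$measure <- measure_label(report$condition, report$run)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$measure, y = .data$z)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, shape = 1,
                         ggplot2::aes(color = .data$flagged)) +
    ggplot2::geom_hline(yintercept = c(-k, k), linetype = "dashed") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "Z-score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
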