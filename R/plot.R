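#' Scatter plot of infant complexity against parental articulation change
#'
#' Per-dyad mean WCM-SE score against the speaker's VSA difference, with
#' the fitted regression line; excluded subjects are drawn hollow.
#'
#' @param result A `study_result` from [run_study()].
#' @param scale Scale to plot; defaults to the primary configured scale.
#' @return A ggplot object.
#' @export
plot_study <- function(result, scale = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_study() requires the ggplot2 package")
  }
  stopifnot(inherits(result, "study_result"))
  scale <- scale %||% result$config$scales[1]
  d <- dplyr::inner_join(result$subject_scores, result$vsa[[scale]]$table,
                         by = c(subject_id = "speaker_id"))
  d$excluded <- d$subject_id %in% result$excluded_subjects$subject_id
  unit <- if (scale == "hz") "Hz²" else "Bark²"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$difference, y = .data$mean_score)) +
    ggplot2::geom_smooth(data = d[!d$excluded, ], method = "lm",
                         formula = y ~ x, se = TRUE, colour = "grey30") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$excluded), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1),
                                guide = "none") +
    ggplot2::labs(x = paste0("VSA difference (IDS − ADS, ", unit, ")"),
                  y = "Mean WCM-SE score") +
    ggplot2::theme_minimal()
}
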