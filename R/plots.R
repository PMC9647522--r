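#' Plot per-ROI area and potential traces
#'
#' Overlay of the normalized TMRM (potential) and mitochondrial
#' area-fraction traces, one panel per signal, lines per ROI — the standard
#' dual-readout view of a movie.
#'
#' @param traces a [mito_traces()] table.
#' @param max_rois cap on the number of ROIs drawn (default 20).
#' @return a ggplot object.
#' @export
plot_traces <- function(traces, max_rois = 20) {
  keep <- head(sort(unique(traces$roi_id)), max_rois)
  long <- traces |>
    filter(.data$roi_id %in% keep) |>
    select("roi_id", "time_s", area = "area_fraction",
           potential = "tmrm_norm") |>
    tidyr::pivot_longer(c("area", "potential"), names_to = "signal")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value,
                                     group = .data$roi_id)) +
    ggplot2::geom_line(alpha = 0.6, linewidth = 0.3) +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          area = "RI mask area fraction",
                          potential = "normalized TMRM"))) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Jitter-plus-mean plot of single-organelle event statistics
#'
#' @param object a [summarize_events()] table.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.mito_events <- function(object, ...) {
  df <- object |>
    filter(!is.na(.data$residual_potential), !is.na(.data$delay_s)) |>
    select("track_id", "residual_potential", "delay_s") |>
    tidyr::pivot_longer(-"track_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$name, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, colour = "red",
                          linewidth = 0.8) +
    ggplot2::facet_wrap(~name, scales = "free",
                        labeller = ggplot2::as_labeller(c(
                          residual_potential = "residual potential (fraction)",
                          delay_s = "onset-to-permeabilization delay (s)"))) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Single-organelle permeabilization statistics (mean ± SEM)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Bar-with-SEM plot of group summaries
#'
#' @param summary a [group_summary()] table.
#' @param ylab y-axis label.
#' @return a ggplot object.
#' @export
plot_group_summary <- function(summary, ylab = "value") {
  ggplot2::ggplot(summary, ggplot2::aes(.data$group, .data$mean)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 0.15) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}
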