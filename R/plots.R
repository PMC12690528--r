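#' Violin summary of per-condition overlap scores
#'
#' Violin plot of per-ROI overlap scores by condition with the median and
#' quartiles drawn as dashed lines, matching the usual presentation of
#' aggregated SMLM overlap scores. Requires `ggplot2`.
#'
#' @param results per-ROI overlap results data.frame (columns
#'   `condition`, `overlap`).
#' @return A ggplot object.
#' @export
plot_overlap_violins <- function(results) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data$condition, y = .data$overlap)) +
    ggplot2::geom_violin(draw_quantiles = c(0.25, 0.5, 0.75),
                         linetype = "dashed") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "overlap score (1 - D)") +
    ggplot2::theme_classic()
}

#' Distance-to-center CDF plot for one ROI
#'
#' @param profile the `profile` element returned by [analyze_roi()].
#' @return A ggplot object with one ECDF curve per channel.
#' @export
plot_distance_cdf <- function(profile) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotting requires the 'ggplot2' package", call. = FALSE)
  df <- do.call(rbind, lapply(names(profile$distances), function(ch) {
    e <- distance_ecdf(profile$distances[[ch]])
    data.frame(channel = ch, x = e$x, F = e$F, stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$F,
                                   colour = .data$channel)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "distance to center (nm)", y = "cumulative fraction",
                  title = profile$roi_id) +
    ggplot2::theme_classic()
}

#' @importFrom stats setNames
#' @keywords internal
"_PACKAGE"
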