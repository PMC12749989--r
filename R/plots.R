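## ggplot2 display methods ------------------------------------------------

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_point
#'   geom_errorbar geom_hline geom_ribbon facet_wrap labs
#'   scale_y_continuous theme_minimal
#' @export
ggplot2::autoplot

#' Plot a state census as monomer and trimer frequency panels
#'
#' Bar panels of the monomer-state and trimer-composition percentages
#' (with bootstrap intervals when present), mirroring the two-panel
#' summary layout used for conformational-state distributions.
#'
#' @param object A `state_census`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot state_census
#' @export
autoplot.state_census <- function(object, ...) {
  mono <- tidy(object, "monomer")
  tri <- tidy(object, "trimer")
  mono <- dplyr::mutate(mono, panel = "monomer states",
                        category = factor(.data$state, levels = STATES))
  tri <- dplyr::mutate(tri, panel = "trimer compositions",
                       category = factor(.data$composition,
                                         levels = tri$composition))
  both <- dplyr::bind_rows(
    mono[, c("panel", "category", "freq",
             intersect(names(mono), c("conf.low", "conf.high")))],
    tri[, c("panel", "category", "freq",
            intersect(names(tri), c("conf.low", "conf.high")))])
  p <- ggplot(both, aes(x = .data$category, y = 100 * .data$freq)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~panel, scales = "free_x") +
    labs(x = NULL, y = "frequency (% of particles)") +
    theme_minimal()
  if ("conf.low" %in% names(both))
    p <- p + geom_errorbar(aes(ymin = 100 * .data$conf.low,
                               ymax = 100 * .data$conf.high), width = 0.25)
  p
}

#' Plot an along-channel clearance profile
#'
#' Clearance against arc length with the bottleneck marked.
#'
#' @param object A `channel_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot channel_result
#' @export
autoplot.channel_result <- function(object, ...) {
  prof <- channel_profile(object)
  ggplot(prof, aes(x = .data$arc_length, y = .data$clearance)) +
    geom_line() + geom_point(size = 0.8) +
    geom_hline(yintercept = object$bottleneck_radius, linetype = "dashed") +
    labs(x = "arc length (Å)", y = "clearance radius (Å)",
         subtitle = sprintf("bottleneck %.2f Å%s",
                            object$bottleneck_radius,
                            if (object$reached_exterior) ""
                            else " (exterior not reached)")) +
    theme_minimal()
}

#' Plot phenotype scores as a variant-by-drug grid
#'
#' Tile grid of signed dilution-step differences (PDA) or fold ratios
#' (MIC), green for gains and purple for losses relative to wildtype.
#'
#' @param scores Output of [pda_score()] (column `score`) or
#'   [mic_normalize()] (column `ratio`, shown as log2 fold change).
#' @return A ggplot object.
#' @export
plot_phenotype_grid <- function(scores) {
  val <- if ("score" %in% names(scores)) scores$score else log2(scores$ratio)
  lab <- if ("score" %in% names(scores)) "steps vs wildtype"
         else "log2 MIC ratio vs wildtype"
  df <- dplyr::mutate(scores, value = val)
  ggplot(df, aes(x = .data$drug, y = .data$variant, fill = .data$value)) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_gradient2(low = "purple4", mid = "white",
                                  high = "darkgreen", name = lab) +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' Plot a replicate time-course summary
#'
#' Mean curve with a standard-deviation ribbon.
#'
#' @param summary Output of [summarize_timecourse()].
#' @return A ggplot object.
#' @export
plot_timecourse <- function(summary) {
  ggplot(summary, aes(x = .data$time, y = .data$mean)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
                fill = "grey80") +
    geom_line() +
    labs(x = "time", y = "signal (mean ± sd)") +
    theme_minimal()
}
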