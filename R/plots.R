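#' Plot percentage of dying tumor over time, per condition
#'
#' Mean trajectory with standard-error bars per condition; optional per-day
#' significance marks (* p < 0.05, \eqn{\dagger} p < 0.01) from
#' [kruskal_by_day()].
#'
#' @param condition_summary the \code{conditions} table from
#'   [dying_timeseries()].
#' @param kw optional per-timepoint test table (columns day, p).
#' @return a ggplot object.
#' @export
plot_dying_timeseries <- function(condition_summary, kw = NULL) {
  d <- condition_summary
  d$pct <- 100 * d$mean_fraction
  d$se_pct <- 100 * d$se_fraction
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_h, y = .data$pct,
                                       color = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$pct - .data$se_pct,
                                        ymax = .data$pct + .data$se_pct),
                           width = 1.5, na.rm = TRUE) +
    ggplot2::labs(x = "Time (h)", y = "Dying tumor (%)",
                  color = "Condition") +
    ggplot2::theme_classic()
  p + add_significance_marks(kw, d$pct + ifelse(is.na(d$se_pct), 0, d$se_pct))
}

#' Plot in vivo tumor growth per group
#'
#' @param growth_summary result of [group_timeseries_summary()].
#' @param kw optional per-day test table (columns day, p).
#' @return a ggplot object.
#' @export
plot_growth_curves <- function(growth_summary, kw = NULL) {
  d <- growth_summary
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$day,
                                       y = .data$mean_volume_mm3,
                                       color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_volume_mm3 - .data$se_volume_mm3,
                   ymax = .data$mean_volume_mm3 + .data$se_volume_mm3),
      width = 0.5, na.rm = TRUE) +
    ggplot2::labs(x = "Day", y = expression(Tumor~volume~(mm^3)),
                  color = "Group") +
    ggplot2::theme_classic()
  p + add_significance_marks(kw,
        d$mean_volume_mm3 + ifelse(is.na(d$se_volume_mm3), 0,
                                   d$se_volume_mm3),
        x_col = "day")
}

add_significance_marks <- function(kw, y_values, x_col = "day") {
  if (is.null(kw) || !nrow(kw)) return(NULL)
  sig <- kw[kw$p < 0.05, , drop = FALSE]
  if (!nrow(sig)) return(NULL)
  sig$mark <- ifelse(sig$p < 0.01, "†", "*")
  y_top <- max(y_values, na.rm = TRUE) * 1.06
  ggplot2::annotate("text", x = sig[[x_col]] %||% sig[[1]], y = y_top,
                    label = sig$mark)
}

#' @importFrom ggplot2 .data
NULL
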