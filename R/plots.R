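#' Cost-effectiveness plane
#'
#' Scatter of PSA draws on the incremental-QALY / incremental-cost
#' plane, with the deterministic estimate, the probabilistic mean and
#' the willingness-to-pay threshold line.
#'
#' @param psa A `cua_psa` from [psa_run()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  s <- psa$samples
  means <- data.frame(delta_qalys = mean(s$delta_qalys),
                      delta_cost = mean(s$delta_cost))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$delta_qalys,
                                  y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.35, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0,
                         linetype = "dashed") +
    ggplot2::geom_point(data = psa$base, shape = 15, size = 3,
                        colour = "firebrick") +
    ggplot2::geom_point(data = means, shape = 17, size = 3,
                        colour = "navy") +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (GBP)",
                  title = sprintf("Cost-effectiveness plane (%d draws)",
                                  nrow(s)))
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param ceac_df Data frame from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_df) {
  ggplot2::ggplot(ceac_df, ggplot2::aes(x = .data$wtp,
                                        y = .data$p_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (GBP/QALY)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' Tornado diagram
#'
#' Horizontal bars for each swept parameter's low/high impact on the
#' chosen outcome, widest swing on top, with the base case as a
#' vertical reference line.
#'
#' @param tornado A `cua_tornado` from [dsa_univariate()].
#' @param outcome `"delta_cost"` or `"nmb"`.
#' @param top Number of parameters to show (widest swings first).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, outcome = c("delta_cost", "nmb"),
                         top = 15) {
  outcome <- match.arg(outcome)
  lo_col <- paste0(outcome, "_low"); hi_col <- paste0(outcome, "_high")
  base <- attr(tornado, if (outcome == "delta_cost") "base_delta_cost"
                        else "base_nmb")
  d <- utils::head(tornado[order(-tornado[[paste0(outcome, "_swing")]],
                                 tornado$parameter), ], top)
  d$parameter <- factor(d$parameter, levels = rev(d$parameter))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data[[lo_col]],
                                       xend = .data[[hi_col]],
                                       yend = .data$parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base, linetype = "dashed") +
    ggplot2::labs(x = if (outcome == "delta_cost")
                        "Incremental cost (GBP)" else "NMB (GBP)",
                  y = NULL, title = "Univariate sensitivity (tornado)")
}

#' Cumulative incremental cost over time
#'
#' Month-by-month cumulative discounted incremental cost; the zero
#' crossing marks the cost-neutral month.
#'
#' @param inc Data frame from [increment_over_time()].
#' @return A ggplot object.
#' @export
plot_increment_over_time <- function(inc) {
  ggplot2::ggplot(inc, ggplot2::aes(x = .data$month, y = .data$delta_cost)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Month", y = "Cumulative incremental cost (GBP)",
                  title = "Incremental cost over time")
}
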