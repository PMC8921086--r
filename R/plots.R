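#' Tornado diagram of one-way sensitivity results
#'
#' Horizontal bars span the incremental NMB (CE-MR/CT minus CE-CT) reached
#' at the low and high end of each parameter's range; the vertical line
#' marks the base-case value.
#'
#' @param x An `mstage_tornado` from [tornado()].
#' @param top Number of widest bars to show (default all).
#' @return A ggplot object.
#' @export
plot_tornado <- function(x, top = nrow(x)) {
  stopifnot(inherits(x, "mstage_tornado"))
  df <- utils::head(as.data.frame(x), top)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$dnmb_low, xend = .data$dnmb_high,
                   yend = .data$parameter),
      linewidth = 4, colour = "steelblue"
    ) +
    ggplot2::geom_vline(xintercept = attr(x, "dnmb_base"), linetype = 2) +
    ggplot2::labs(
      x = sprintf("Incremental NMB of CE-MR/CT vs CE-CT ($, WTP $%s/QALY)",
                  format(attr(x, "wtp"), big.mark = ",")),
      y = NULL, title = "One-way deterministic sensitivity analysis"
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  ggplot2::ggplot(psa$ceac, ggplot2::aes(.data$wtp, .data$p_cemrct)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness-to-pay ($/QALY)",
                  y = "P(CE-MR/CT cost-effective)",
                  title = "Cost-effectiveness acceptability curve") +
    ggplot2::theme_minimal()
}

#' Incremental cost-effectiveness scatter of PSA iterations
#'
#' @param psa A `psa_result`.
#' @param max_points Subsample size for plotting (default 2000).
#' @param wtp WTP threshold line to draw.
#' @return A ggplot object.
#' @export
plot_psa_scatter <- function(psa, max_points = 2000L,
                             wtp = 100000) {
  stopifnot(inherits(psa, "psa_result"))
  df <- psa$draws
  if (nrow(df) > max_points) df <- df[seq_len(max_points), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::labs(x = "Incremental QALYs (CE-MR/CT - CE-CT)",
                  y = "Incremental cost ($)",
                  title = "PSA incremental cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' NMB of both strategies versus the resectability-classification probability
#'
#' @param th A `threshold_result` from [threshold_resectability()].
#' @return A ggplot object.
#' @export
plot_threshold <- function(th) {
  stopifnot(inherits(th, "threshold_result"))
  curve <- th$curve
  df <- rbind(
    data.frame(p = curve$p, nmb = curve$nmb_cect, strategy = "CE-CT"),
    data.frame(p = curve$p, nmb = curve$nmb_cemrct, strategy = "CE-MR/CT")
  )
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$p, .data$nmb,
                                        colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "P(correct resectability classification on CT)",
                  y = "Net monetary benefit ($)",
                  title = "NMB versus resectability classification accuracy",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (!th$no_crossover) {
    g <- g + ggplot2::geom_vline(xintercept = th$crossover, linetype = 2)
  }
  g
}
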