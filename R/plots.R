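#' Cost-effectiveness plane scatter of PSA simulations
#'
#' @param psa An `iris_psa` result.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- psa$draws
  ggplot2::ggplot(d, ggplot2::aes(x = inc_qaly, y = inc_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = psa$wtp, intercept = 0, colour = "grey40") +
    ggplot2::labs(x = "Incremental QALYs per woman",
                  y = "Incremental cost per woman (GBP 2015/16)",
                  title = "Cost-effectiveness plane",
                  subtitle = sprintf("%d simulations; line: WTP %s/QALY",
                                     nrow(d), format(psa$wtp, big.mark = ",")))
}

#' Cost-effectiveness acceptability curve
#'
#' @param psa An `iris_psa` result (or a data frame from [ceac()]).
#' @return A ggplot object.
#' @export
plot_ceac <- function(psa) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- if (inherits(psa, "iris_psa")) psa$ceac else psa
  ggplot2::ggplot(d, ggplot2::aes(x = wtp, y = probability)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay per QALY (GBP 2015/16)",
                  y = "Probability cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}
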