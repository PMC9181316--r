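#' Quick-look figures for the four kit-quality analyses
#'
#' Each function accepts either a [run_pipeline()] result or the
#' corresponding metric tibble. `autoplot()` dispatches on `which`.
#'
#' @param x A `strwga_run` or the metric tibble.
#' @return A ggplot object.
#' @name strwga-plots
NULL

pick_table <- function(x, name) {
  if (inherits(x, "strwga_run")) x[[name]] else x
}

#' @rdname strwga-plots
#' @export
plot_coverage <- function(x) {
  d <- pick_table(x, "coverage")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kit, y = .data$loci_sampled)) +
    ggplot2::geom_jitter(ggplot2::aes(colour = .data$failed), width = 0.2,
                         height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = "loci sampled per cell",
                  colour = "failed") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname strwga-plots
#' @export
plot_balance <- function(x) {
  d <- pick_table(x, "balance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kit, y = .data$w)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = NULL, y = "shorter-allele proportion w") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname strwga-plots
#' @export
plot_consistency <- function(x) {
  d <- pick_table(x, "consistency")
  d <- d[!is.na(d$mean_intersection), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$mean_intersection,
                                  colour = .data$kit)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "cells in group (k)",
                  y = "mean jointly sampled loci", colour = NULL) +
    ggplot2::theme_bw()
}

#' @rdname strwga-plots
#' @export
plot_noise <- function(x) {
  d <- pick_table(x, "noise")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kit, y = .data$median_cycles)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.2, height = 0, size = 1.5) +
    ggplot2::labs(x = NULL, y = "median fitted cycles per cell") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @rdname strwga-plots
#' @param object A `strwga_run`.
#' @param which One of `"coverage"`, `"balance"`, `"consistency"`,
#'   `"noise"`.
#' @param ... Unused.
#' @export
autoplot.strwga_run <- function(object, which = "coverage", ...) {
  switch(match.arg(which, c("coverage", "balance", "consistency", "noise")),
         coverage = plot_coverage(object),
         balance = plot_balance(object),
         consistency = plot_consistency(object),
         noise = plot_noise(object))
}
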