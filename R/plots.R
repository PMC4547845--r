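# ggplot2 views of the main result types.

#' Parental-versus-allelic PSI difference scatter
#'
#' The classic cis/trans dissection view: each retained event's parental
#' PSI difference against its allelic difference in the hybrid, coloured by
#' final category. Pure-cis events fall on the diagonal (the allelic
#' difference reproduces the parental one); pure-trans events on the
#' horizontal axis.
#'
#' @param result A `cistrans_result`.
#' @return A ggplot object.
#' @export
plot_cis_trans <- function(result) {
  d <- result$classification |>
    left_join(result$calls_parental$calls |>
                select("event_id", parental_delta = "mean_delta_psi"),
              by = "event_id") |>
    left_join(result$calls_allelic$calls |>
                select("event_id", allelic_delta = "mean_delta_psi"),
              by = "event_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$allelic_delta,
                                  y = .data$parental_delta,
                                  colour = .data$category)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::labs(x = "allelic ΔPSI (F1 hybrid)",
                  y = "parental ΔPSI", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Permutation FDR against the PSI-difference cutoff
#'
#' @param fdr_grid Tibble from [permutation_fdr()] (or a `cistrans_result`,
#'   whose grid is used).
#' @return A ggplot object.
#' @export
plot_fdr_grid <- function(fdr_grid) {
  if (inherits(fdr_grid, "cistrans_result")) fdr_grid <- fdr_grid$fdr_grid
  ggplot2::ggplot(fdr_grid, ggplot2::aes(x = .data$cutoff, y = .data$fdr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$fdr_mean - 2 * .data$fdr_sd, 0),
                                      ymax = .data$fdr_mean + 2 * .data$fdr_sd),
                         fill = "grey85") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "|ΔPSI| cutoff", y = "estimated FDR") +
    ggplot2::theme_minimal()
}

#' Mock-filter MA-style view
#'
#' Parental-minus-mock PSI difference against mock coverage, with the local
#' standard-deviation band and dropped events highlighted.
#'
#' @param mock_filter Output of [run_mock_filter()] (or a `cistrans_result`).
#' @return A ggplot object.
#' @export
plot_mock_filter <- function(mock_filter) {
  if (inherits(mock_filter, "cistrans_result")) mock_filter <- mock_filter$mock_filter
  d <- mock_filter$result
  ggplot2::ggplot(d, ggplot2::aes(x = .data$coverage, y = .data$delta)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$verdict), alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = 2 * .data$sigma_local), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = -2 * .data$sigma_local), linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(keep = "grey40",
                                            drop_inconsistent = "red")) +
    ggplot2::labs(x = "mock allelic coverage (reads)",
                  y = "parental - mock PSI", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname plot_cis_trans
#' @param object A `cistrans_result`.
#' @param ... Unused.
#' @export
autoplot.cistrans_result <- function(object, ...) {
  plot_cis_trans(object)
}
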