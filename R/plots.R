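#' Kaplan-Meier plot of a survival comparison
#'
#' @param object A `crgi_surv` object.
#' @param ... Unused.
#' @return A ggplot: per-group survival step curves.
#' @export
autoplot.crgi_surv <- function(object, ...) {
  if (is.null(object$km)) abort("degenerate survival comparison; nothing to plot")
  km <- dplyr::bind_rows(
    purrr::map_dfr(split(object$km, object$km$group), function(d) {
      tibble::tibble(group = d$group[[1]], time = 0, surv = 1)
    }),
    object$km[, c("group", "time", "surv")]
  )
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Degree distribution of an interaction network
#'
#' Log-log degree histogram of genes and drugs, the standard display for
#' checking scale-free-like behaviour.
#'
#' @param object An `interaction_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.interaction_network <- function(object, ...) {
  deg <- degree_table(object)
  counts <- dplyr::count(dplyr::filter(deg, .data$degree > 0),
                         .data$kind, .data$degree)
  ggplot2::ggplot(counts, ggplot2::aes(.data$degree, .data$n,
                                       colour = .data$kind)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Nodes", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano-style view of a differential-feature table
#'
#' @param diff Result of [differential_features()].
#' @param fdr FDR threshold drawn on the plot (default 0.1).
#' @return A ggplot of the per-feature directional adjusted p-values.
#' @export
plot_differential <- function(diff, fdr = 0.1) {
  tbl <- dplyr::mutate(
    diff$table,
    direction = dplyr::case_when(.data$q_up < fdr ~ "up",
                                 .data$q_down < fdr ~ "down",
                                 TRUE ~ "ns"),
    score = -log10(pmin(.data$q_up, .data$q_down))
  )
  ggplot2::ggplot(tbl, ggplot2::aes(.data$q_down, .data$q_up,
                                    colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "BH-adjusted p (down)", y = "BH-adjusted p (up)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Null distribution of the PPI overlap permutation test
#'
#' @param overlap Result of [ppi_overlap_test()].
#' @return A ggplot: histogram of null contact rates with the observed rate
#'   marked.
#' @export
plot_ppi_overlap <- function(overlap) {
  nulls <- tibble::tibble(rate = overlap$null_rates[[1]])
  ggplot2::ggplot(nulls, ggplot2::aes(.data$rate)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = overlap$observed_rate,
                        colour = "firebrick", linewidth = 0.8) +
    ggplot2::labs(x = "PPI contact rate", y = "Null replicates") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
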