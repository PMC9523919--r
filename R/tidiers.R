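#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a test result
#'
#' @param x A `crgi_test` row (rank-sum, t, chi-square or log-rank result).
#' @param ... Unused.
#' @return A one-row tibble with `statistic`, `p.value`, `method` and group
#'   sizes, following broom naming conventions.
#' @export
tidy.crgi_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 alternative = x$alternative, method = x$method,
                 n.x = x$n_x, n.y = x$n_y)
}

#' Tidy a survival comparison
#'
#' @param x A `crgi_surv` object from [compare_survival()] or
#'   [single_pair_survival()].
#' @param ... Unused.
#' @return The per-group Kaplan-Meier step table (empty when degenerate).
#' @export
tidy.crgi_surv <- function(x, ...) {
  if (is.null(x$km)) return(tibble::tibble())
  x$km
}

#' One-row summary of a survival comparison
#' @inheritParams tidy.crgi_surv
#' @return Tibble with the log-rank statistic, df, p-value and group count.
#' @export
glance.crgi_surv <- function(x, ...) {
  if (is.null(x$test)) {
    return(tibble::tibble(statistic = NA_real_, df = NA_integer_,
                          p.value = NA_real_, n.groups = NA_integer_,
                          degenerate = TRUE))
  }
  tibble::tibble(statistic = x$test$statistic, df = x$test$df,
                 p.value = x$test$p_value,
                 n.groups = length(unique(x$groups$group)),
                 degenerate = x$degenerate)
}

#' One-row summary of an interaction network
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble with node and edge counts.
#' @export
glance.interaction_network <- function(x, ...) {
  tibble::tibble(n.genes = length(x$genes), n.drugs = length(x$drugs),
                 n.gene.edges = nrow(x$gene_edges),
                 n.drug.edges = nrow(x$drug_edges))
}

#' Tidy an interaction network into an edge table
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble `from`, `to`, `edge_type` covering gene-gene and
#'   drug-gene edges.
#' @export
tidy.interaction_network <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(from = x$gene_edges$gene_a, to = x$gene_edges$gene_b,
                   edge_type = "gene-gene"),
    tibble::tibble(from = x$drug_edges$drug, to = x$drug_edges$gene,
                   edge_type = "drug-gene")
  )
}
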