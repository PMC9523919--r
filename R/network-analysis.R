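#' Build a gene-drug interaction network
#'
#' Nodes are genes and drugs; undirected gene-gene edges come from the
#' interactions and drug-gene edges link each drug to the interaction
#' target it hits. Duplicate edges are collapsed.
#'
#' @param records Drug-interaction records (or plain interaction records;
#'   a `drug` column is optional).
#' @return An object of class `interaction_network` with tibbles
#'   `gene_edges` (gene_a, gene_b, itype, tissue) and `drug_edges`
#'   (drug, gene), plus node sets `genes` and `drugs`.
#' @export
build_network <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    return(structure(list(genes = character(0), drugs = character(0),
                          gene_edges = tibble::tibble(gene_a = character(0),
                                                      gene_b = character(0),
                                                      itype = character(0),
                                                      tissue = character(0)),
                          drug_edges = tibble::tibble(drug = character(0),
                                                      gene = character(0))),
                     class = "interaction_network"))
  }
  col_or_na <- function(nm) {
    if (nm %in% names(records)) records[[nm]] else NA_character_
  }
  gene_edges <- dplyr::distinct(tibble::tibble(
    gene_a = pmin(records$target, records$partner),
    gene_b = pmax(records$target, records$partner),
    itype = col_or_na("itype"),
    tissue = col_or_na("tissue")
  ))
  drug_edges <- if ("drug" %in% names(records)) {
    dplyr::distinct(tibble::tibble(drug = records$drug, gene = records$target))
  } else {
    tibble::tibble(drug = character(0), gene = character(0))
  }
  genes <- sort(unique(c(gene_edges$gene_a, gene_edges$gene_b, drug_edges$gene)))
  drugs <- sort(unique(drug_edges$drug))
  structure(list(genes = genes, drugs = drugs,
                 gene_edges = gene_edges, drug_edges = drug_edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network>\n",
      "  genes: ", length(x$genes), ", drugs: ", length(x$drugs), "\n",
      "  gene-gene edges: ", nrow(x$gene_edges),
      ", drug-gene edges: ", nrow(x$drug_edges), "\n", sep = "")
  invisible(x)
}

network_igraph <- function(network) {
  edges <- rbind(
    as.matrix(network$gene_edges[, c("gene_a", "gene_b")]),
    as.matrix(setNames(network$drug_edges[, c("drug", "gene")],
                       c("gene_a", "gene_b")))
  )
  igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = data.frame(name = c(network$genes, network$drugs))
  )
}

#' Node degrees of the union (gene + drug) graph
#'
#' @param network An [build_network()] result.
#' @return Tibble `node`, `kind` (gene/drug), `degree`, sorted by
#'   decreasing degree.
#' @export
degree_table <- function(network) {
  g <- network_igraph(network)
  deg <- igraph::degree(g)
  tibble::tibble(node = names(deg),
                 kind = ifelse(names(deg) %in% network$drugs, "drug", "gene"),
                 degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}

ppi_adjacency <- function(ppi) {
  ends <- c(ppi$gene_a, ppi$gene_b)
  nbrs <- c(ppi$gene_b, ppi$gene_a)
  split(nbrs, ends)
}

pair_contact <- function(adj, a, b, max_path = 2) {
  na <- adj[[a]]
  if (is.null(na)) return(FALSE)
  if (b %in% na) return(TRUE)
  if (max_path < 2) return(FALSE)
  nb <- adj[[b]]
  if (is.null(nb)) return(FALSE)
  length(intersect(na, nb)) > 0
}

#' Permutation test of PPI contact enrichment
#'
#' Measures the fraction of the network's gene pairs in direct contact (a
#' PPI edge) or indirect contact (shortest PPI path of length 2, i.e. a
#' shared neighbour), and compares it to a null in which the same number of
#' gene pairs is drawn uniformly, without replacement within a replicate
#' and excluding self-pairs, from the genes having at least one PPI edge.
#' The empirical p carries a +1 pseudocount so it is never zero:
#' `(1 + #\{null rate >= observed\}) / (1 + n_perm)`.
#'
#' @param network An [build_network()] result with >= 1 gene-gene edge.
#' @param ppi A [ppi_graph()].
#' @param n_perm Number of null replicates (default 1000).
#' @param seed Integer seed for reproducibility.
#' @param max_path Maximum PPI path length counted as contact (default 2).
#' @return One-row tibble: `observed_rate`, `empirical_p`, `n_pairs`,
#'   `n_perm`, plus the null rates as list-column `null_rates`.
#' @export
ppi_overlap_test <- function(network, ppi, n_perm = 1000, seed = 1L,
                             max_path = 2) {
  if (nrow(ppi) == 0) abort("ppi_overlap_test: empty PPI graph")
  pairs <- network$gene_edges
  if (nrow(pairs) == 0) abort("ppi_overlap_test: network has no gene-gene edges")
  if (n_perm < 1) abort("ppi_overlap_test: n_perm must be >= 1")
  adj <- ppi_adjacency(ppi)
  observed <- mean(purrr::map2_lgl(pairs$gene_a, pairs$gene_b,
                                   ~pair_contact(adj, .x, .y, max_path)))
  universe <- names(adj)
  m <- nrow(pairs)
  null_rates <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      drawn <- character(0)
      rates <- logical(m)
      k <- 0
      while (k < m) {
        g <- sample(universe, 2)
        key <- paste(sort(g), collapse = "\r")
        if (key %in% drawn) next
        drawn <- c(drawn, key)
        k <- k + 1
        rates[k] <- pair_contact(adj, g[[1]], g[[2]], max_path)
      }
      mean(rates)
    }, numeric(1))
  })
  tibble::tibble(
    observed_rate = observed,
    empirical_p = (1 + sum(null_rates >= observed)) / (1 + n_perm),
    n_pairs = m, n_perm = as.integer(n_perm),
    null_rates = list(null_rates)
  )
}

# Evaluate `code` under a local RNG seed without touching the global stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Cancer-gene enrichment of network chromatin regulators
#'
#' 2x2 chi-square comparing the cancer-gene fraction among chromatin
#' regulators inside the network against the remaining background
#' regulators.
#'
#' @param network_crs Chromatin regulators present in the network.
#' @param background_crs Full chromatin-regulator list (must contain
#'   `network_crs`).
#' @param cancer_genes Cancer-gene census set.
#' @return One-row `crgi_test` tibble with the 2x2 counts attached as
#'   columns `in_cancer`, `in_other`, `out_cancer`, `out_other`.
#' @export
cancer_gene_enrichment <- function(network_crs, background_crs, cancer_genes) {
  if (length(network_crs) == 0) abort("cancer_gene_enrichment: empty network set")
  if (!all(network_crs %in% background_crs)) {
    abort("cancer_gene_enrichment: network CRs must be a subset of background")
  }
  rest <- setdiff(background_crs, network_crs)
  a <- sum(network_crs %in% cancer_genes)
  b <- length(network_crs) - a
  c_ <- sum(rest %in% cancer_genes)
  d <- length(rest) - c_
  out <- chi_square_2x2(a, b, c_, d)
  dplyr::mutate(out, in_cancer = a, in_other = b, out_cancer = c_, out_other = d)
}

#' Induced subnetwork around a hub gene
#'
#' Returns the subgraph induced by the gene, its gene neighbours, and the
#' drugs incident to the gene.
#'
#' @param network An [build_network()] result.
#' @param gene Hub gene symbol (must be a network node).
#' @return An `interaction_network` restricted to the hub neighbourhood.
#' @export
hub_subnetwork <- function(network, gene) {
  if (!gene %in% network$genes) abort(paste0("gene not in network: ", gene))
  nbrs <- unique(c(
    network$gene_edges$gene_b[network$gene_edges$gene_a == gene],
    network$gene_edges$gene_a[network$gene_edges$gene_b == gene]
  ))
  keep_genes <- c(gene, nbrs)
  keep_drugs <- unique(network$drug_edges$drug[network$drug_edges$gene == gene])
  structure(list(
    genes = sort(keep_genes), drugs = sort(keep_drugs),
    gene_edges = dplyr::filter(network$gene_edges,
                               .data$gene_a %in% keep_genes,
                               .data$gene_b %in% keep_genes),
    drug_edges = dplyr::filter(network$drug_edges,
                               .data$drug %in% keep_drugs,
                               .data$gene %in% keep_genes)
  ), class = "interaction_network")
}
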