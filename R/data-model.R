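#' Construct a perturbation screen dataset
#'
#' A screen holds a gene-by-cell-line matrix of dependency (fitness) scores
#' together with an orientation flag declaring which direction of the score
#' means "more viable". CRISPR CERES-style scores are `"low_is_viable"`
#' (lower = more essential, i.e. higher = more viable is FALSE: a *low*
#' score means the knockout hurt the cell, so high scores are *less*
#' depleted — CERES publishes essentiality, hence low = viable is the
#' orientation flag we need to flip); Sanger fitness and shRNA dependency
#' scores are `"high_is_viable"`.
#'
#' @param scores Numeric matrix, genes in rows, cell lines in columns, with
#'   row and column names. Entries must be finite or `NA`.
#' @param lineages Data frame with columns `cell_line`, `tissue`, or a named
#'   character vector mapping cell line to tissue. Every column of `scores`
#'   must be covered.
#' @param name Screen label used in result tables.
#' @param orientation `"high_is_viable"` or `"low_is_viable"`.
#' @return An object of class `screen_dataset`.
#' @export
screen_dataset <- function(scores, lineages, name,
                           orientation = c("high_is_viable", "low_is_viable")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    abort("`scores` must be a numeric matrix")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    abort("`scores` must have gene rownames and cell-line colnames")
  }
  bad <- is.infinite(scores)
  if (any(bad)) abort("`scores` contains non-finite entries; use NA for missing")
  lineages <- as_lineage_tbl(lineages)
  missing_lines <- setdiff(colnames(scores), lineages$cell_line)
  if (length(missing_lines) > 0) {
    abort(paste0("cell lines without a tissue label: ",
                 paste(head(missing_lines, 5), collapse = ", ")))
  }
  structure(
    list(name = as.character(name), orientation = orientation,
         scores = scores,
         lineages = dplyr::filter(lineages, .data$cell_line %in% colnames(scores))),
    class = "screen_dataset"
  )
}

as_lineage_tbl <- function(lineages) {
  if (is.data.frame(lineages)) {
    if (!all(c("cell_line", "tissue") %in% names(lineages))) {
      abort("`lineages` needs columns cell_line, tissue")
    }
    tbl <- tibble::as_tibble(lineages[, c("cell_line", "tissue")])
  } else if (is.character(lineages) && !is.null(names(lineages))) {
    tbl <- tibble::tibble(cell_line = names(lineages), tissue = unname(lineages))
  } else {
    abort("`lineages` must be a data frame or a named character vector")
  }
  if (anyDuplicated(tbl$cell_line)) abort("duplicated cell line in `lineages`")
  tbl
}

#' @export
print.screen_dataset <- function(x, ...) {
  cat("<screen_dataset> ", x$name, "\n",
      "  genes: ", nrow(x$scores), ", cell lines: ", ncol(x$scores), "\n",
      "  orientation: ", x$orientation, "\n",
      "  tissues: ", length(unique(x$lineages$tissue)), "\n", sep = "")
  invisible(x)
}

MUTATION_CLASSES <- c("missense", "nonsense", "frameshift", "splice", "other", "silent")

#' Construct a mutation catalog
#'
#' Tidies a table of per-sample mutation calls. Unknown mutation classes are
#' mapped to `"other"`; `"silent"` calls are retained but flagged as
#' non-altering, because by default an "alteration" is any non-silent
#' mutation.
#'
#' @param records Data frame with columns `sample`, `gene`, `mutation_class`.
#' @param altering_classes Character vector of classes that count as
#'   alterations. Defaults to all non-silent classes.
#' @return A tibble of class `mutation_catalog` with a logical `altering`
#'   column; duplicate (sample, gene, class) triples are collapsed.
#' @export
mutation_catalog <- function(records,
                             altering_classes = setdiff(MUTATION_CLASSES, "silent")) {
  need <- c("sample", "gene", "mutation_class")
  if (!all(need %in% names(records))) {
    abort(paste0("mutation table must have columns: ", paste(need, collapse = ", ")))
  }
  tbl <- tibble::as_tibble(records[, need])
  if (any(!nzchar(tbl$gene) | is.na(tbl$gene))) abort("empty gene symbol in mutation table")
  tbl <- dplyr::mutate(
    tbl,
    mutation_class = ifelse(.data$mutation_class %in% MUTATION_CLASSES,
                            .data$mutation_class, "other"),
    altering = .data$mutation_class %in% altering_classes
  )
  tbl <- dplyr::distinct(tbl)
  class(tbl) <- c("mutation_catalog", class(tbl))
  tbl
}

#' Samples carrying an altering mutation in a gene
#'
#' @param mutations A [mutation_catalog()].
#' @param gene Gene symbol.
#' @return Character vector of sample identifiers.
#' @export
altered_samples <- function(mutations, gene) {
  unique(mutations$sample[mutations$gene == gene & mutations$altering])
}

#' Construct a drug-response dataset
#'
#' Drug-by-cell-line response summaries (IC50 or AUC). For both metrics a
#' lower value means greater sensitivity.
#'
#' @param responses Numeric matrix, drugs in rows, cell lines in columns.
#' @param lineages As in [screen_dataset()].
#' @param name Dataset label.
#' @param metric `"IC50"` or `"AUC"`.
#' @return An object of class `drug_response_dataset`.
#' @export
drug_response_dataset <- function(responses, lineages, name, metric = c("AUC", "IC50")) {
  metric <- match.arg(metric)
  if (!is.matrix(responses) || !is.numeric(responses)) {
    abort("`responses` must be a numeric matrix")
  }
  if (is.null(rownames(responses)) || is.null(colnames(responses))) {
    abort("`responses` must have drug rownames and cell-line colnames")
  }
  lineages <- as_lineage_tbl(lineages)
  missing_lines <- setdiff(colnames(responses), lineages$cell_line)
  if (length(missing_lines) > 0) {
    abort(paste0("cell lines without a tissue label: ",
                 paste(head(missing_lines, 5), collapse = ", ")))
  }
  structure(
    list(name = as.character(name), metric = metric, responses = responses,
         lineages = dplyr::filter(lineages, .data$cell_line %in% colnames(responses))),
    class = "drug_response_dataset"
  )
}

#' @export
print.drug_response_dataset <- function(x, ...) {
  cat("<drug_response_dataset> ", x$name, " (", x$metric, ")\n",
      "  drugs: ", nrow(x$responses), ", cell lines: ", ncol(x$responses), "\n",
      sep = "")
  invisible(x)
}

#' Construct a patient cohort bundle
#'
#' A TCGA-like bundle: expression and methylation matrices (gene x sample),
#' a mutation catalog, survival records, and optional per-sample scores
#' (HRD components, immune-cell fractions) and a feature-by-sample matrix
#' (e.g. chromatin-accessibility peaks). All assays must share the
#' expression matrix's sample set; mutation and survival samples must be
#' subsets of it.
#'
#' @param expression Gene-by-sample numeric matrix.
#' @param survival Data frame with columns `sample`, `time` (days, >= 0),
#'   `event` (0/1).
#' @param mutations A [mutation_catalog()] or data frame coercible to one.
#' @param methylation Optional gene-by-sample matrix.
#' @param sample_scores Optional score-by-sample matrix.
#' @param feature_matrix Optional feature-by-sample matrix.
#' @param cancer_type Label for the cohort.
#' @return An object of class `cohort`.
#' @export
cohort <- function(expression, survival, mutations, methylation = NULL,
                   sample_scores = NULL, feature_matrix = NULL,
                   cancer_type = "synthetic") {
  if (!is.matrix(expression) || is.null(colnames(expression))) {
    abort("`expression` must be a matrix with sample colnames")
  }
  samples <- colnames(expression)
  if (!all(c("sample", "time", "event") %in% names(survival))) {
    abort("`survival` needs columns sample, time, event")
  }
  survival <- tibble::as_tibble(survival[, c("sample", "time", "event")])
  if (any(survival$time < 0, na.rm = TRUE)) abort("negative survival time")
  if (!all(survival$event %in% c(0, 1))) abort("survival `event` must be 0/1")
  if (!all(survival$sample %in% samples)) {
    abort("survival samples not present in expression matrix")
  }
  if (!inherits(mutations, "mutation_catalog")) mutations <- mutation_catalog(mutations)
  if (!all(mutations$sample %in% samples)) {
    abort("mutation samples not present in expression matrix")
  }
  for (nm in c("methylation", "sample_scores", "feature_matrix")) {
    m <- get(nm)
    if (!is.null(m) && !setequal(colnames(m), samples)) {
      abort(paste0("`", nm, "` samples differ from expression samples"))
    }
  }
  structure(
    list(expression = expression,
         methylation = if (!is.null(methylation)) methylation[, samples, drop = FALSE],
         mutations = mutations, survival = survival,
         sample_scores = if (!is.null(sample_scores)) sample_scores[, samples, drop = FALSE],
         feature_matrix = if (!is.null(feature_matrix)) feature_matrix[, samples, drop = FALSE],
         cancer_type = cancer_type),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", x$cancer_type, "\n",
      "  samples: ", ncol(x$expression),
      ", genes (expression): ", nrow(x$expression), "\n",
      "  methylation: ", if (is.null(x$methylation)) "absent" else nrow(x$methylation),
      ", sample scores: ", if (is.null(x$sample_scores)) "absent" else nrow(x$sample_scores), "\n",
      "  events: ", sum(x$survival$event), "/", nrow(x$survival), "\n", sep = "")
  invisible(x)
}

#' Samples of a cohort
#' @param x A [cohort()].
#' @return Character vector of sample identifiers.
#' @export
cohort_samples <- function(x) colnames(x$expression)

#' Construct a protein-protein interaction edge table
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` (one undirected
#'   edge per row). Self-loops are an error; duplicate edges (in either
#'   order) are collapsed.
#' @return A tibble of class `ppi_graph` with canonically ordered endpoints.
#' @export
ppi_graph <- function(edges) {
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    abort("`edges` needs columns gene_a, gene_b")
  }
  tbl <- tibble::as_tibble(edges[, c("gene_a", "gene_b")])
  if (any(tbl$gene_a == tbl$gene_b)) abort("PPI self-loop")
  a <- pmin(tbl$gene_a, tbl$gene_b)
  b <- pmax(tbl$gene_a, tbl$gene_b)
  tbl <- dplyr::distinct(tibble::tibble(gene_a = a, gene_b = b))
  class(tbl) <- c("ppi_graph", class(tbl))
  tbl
}

#' Construct a drug-to-target map
#'
#' @param pairs Data frame with columns `drug`, `target`.
#' @return A tibble of class `drug_target_map` (distinct rows).
#' @export
drug_target_map <- function(pairs) {
  if (!all(c("drug", "target") %in% names(pairs))) {
    abort("`pairs` needs columns drug, target")
  }
  tbl <- dplyr::distinct(tibble::as_tibble(pairs[, c("drug", "target")]))
  if (any(!nzchar(tbl$target))) abort("empty target gene in drug-target map")
  class(tbl) <- c("drug_target_map", class(tbl))
  tbl
}
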