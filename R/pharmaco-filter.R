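#' Pair consensus interactions with drugs hitting their targets
#'
#' @param interactions Tibble of interaction records ([consensus()]).
#' @param targets A [drug_target_map()].
#' @return Tibble: one row per (interaction, drug) with the drug's target
#'   set containing the interaction's target gene.
#' @export
map_interactions_to_drugs <- function(interactions, targets) {
  dplyr::inner_join(interactions, tibble::as_tibble(targets),
                    by = "target", relationship = "many-to-many")
}

#' Test drug response against partner mutation status
#'
#' For each (interaction, drug) pair, compares IC50/AUC of partner-mutated
#' versus wild-type cell lines in the interaction's tissue with a one-sided
#' rank-sum test. Synthetic-lethal interactions predict *sensitivity*
#' (mutant responses lower, since low IC50/AUC means sensitive);
#' synthetic-viable interactions predict *resistance* (mutant responses
#' higher). Records are retained when p < `alpha`.
#'
#' @param drug_pairs Output of [map_interactions_to_drugs()].
#' @param dataset A [drug_response_dataset()].
#' @param mutations A [mutation_catalog()] over the dataset's cell lines.
#' @param min_group Minimum mutant and wild-type group size (default 3).
#' @param min_lines Minimum cell lines in the tissue with a measured
#'   response for the drug (default 4, i.e. more than three).
#' @param alpha Significance threshold (default 0.05).
#' @param keep_all Keep rejected/skipped rows with their reason.
#' @return Tibble of drug-interaction records: interaction fields + `drug`,
#'   `pharmaco_dataset`, `metric`, `drug_p`, `direction`
#'   (`"SENSITIVE"`/`"RESISTANT"`), `n_mut_drug`, `n_wt_drug`, `retained`,
#'   `reason`.
#' @export
drug_response_test <- function(drug_pairs, dataset, mutations, min_group = 3,
                               min_lines = 4, alpha = 0.05, keep_all = FALSE) {
  stopifnot(inherits(dataset, "drug_response_dataset"))
  lineages <- dataset$lineages
  out <- purrr::pmap_dfr(
    list(seq_len(nrow(drug_pairs))),
    function(i) {
      rec <- drug_pairs[i, ]
      base <- dplyr::select(rec, -dplyr::any_of(c("drug")))
      base$drug <- rec$drug
      base$pharmaco_dataset <- dataset$name
      base$metric <- dataset$metric
      skip <- function(reason) {
        dplyr::mutate(base, drug_p = NA_real_, direction = NA_character_,
                      n_mut_drug = NA_integer_, n_wt_drug = NA_integer_,
                      retained = FALSE, reason = reason)
      }
      if (!rec$drug %in% rownames(dataset$responses)) return(skip("drug_not_measured"))
      lines <- lineages$cell_line[lineages$tissue == rec$tissue]
      resp <- dataset$responses[rec$drug, lines]
      resp <- resp[!is.na(resp)]
      if (length(resp) < min_lines) return(skip("tissue_below_min_lines"))
      mut_lines <- altered_samples(mutations, rec$partner)
      mut <- resp[names(resp) %in% mut_lines]
      wt <- resp[!(names(resp) %in% mut_lines)]
      if (length(mut) < min_group || length(wt) < min_group) {
        return(skip("group_below_min"))
      }
      alt <- if (rec$itype == "CSL") "less" else "greater"
      p <- rank_sum_core(mut, wt, alt)$p_value
      dplyr::mutate(base,
                    drug_p = p,
                    direction = if (rec$itype == "CSL") "SENSITIVE" else "RESISTANT",
                    n_mut_drug = length(mut), n_wt_drug = length(wt),
                    retained = p < alpha, reason = NA_character_)
    })
  if (!keep_all) out <- dplyr::filter(out, .data$retained)
  out
}

#' Run the pharmacogenomic filter over several datasets
#'
#' @param interactions Consensus interaction records.
#' @param targets A [drug_target_map()].
#' @param datasets List of [drug_response_dataset()]s.
#' @param mutation_catalogs Named list of [mutation_catalog()]s keyed by
#'   dataset name, or one shared catalog.
#' @inheritParams drug_response_test
#' @return Combined tibble of drug-interaction records across datasets.
#' @export
pharmaco_filter <- function(interactions, targets, datasets, mutation_catalogs,
                            min_group = 3, min_lines = 4, alpha = 0.05,
                            keep_all = FALSE) {
  drug_pairs <- map_interactions_to_drugs(interactions, targets)
  if (nrow(drug_pairs) == 0) return(tibble::tibble())
  if (inherits(mutation_catalogs, "mutation_catalog")) {
    mutation_catalogs <- setNames(
      rep(list(mutation_catalogs), length(datasets)),
      vapply(datasets, `[[`, character(1), "name"))
  }
  purrr::map_dfr(datasets, function(ds) {
    muts <- mutation_catalogs[[ds$name]]
    if (is.null(muts)) abort(paste0("no mutation catalog for dataset ", ds$name))
    drug_response_test(drug_pairs, ds, muts, min_group = min_group,
                       min_lines = min_lines, alpha = alpha, keep_all = keep_all)
  })
}

#' Summarise drug evidence per (interaction, drug)
#'
#' One row per (target, partner, tissue, itype, drug) listing the
#' pharmacogenomic datasets supporting it and their p-values.
#'
#' @param records Retained drug-interaction records.
#' @return Tibble with `n_datasets`, `datasets` (list-column) and
#'   `drug_p` (named list-column of per-dataset p-values).
#' @export
aggregate_drug_evidence <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(target = character(0), partner = character(0),
                          tissue = character(0), itype = character(0),
                          drug = character(0), direction = character(0),
                          n_datasets = integer(0), datasets = list(),
                          drug_p = list()))
  }
  dplyr::summarise(
    dplyr::group_by(records, .data$target, .data$partner, .data$tissue,
                    .data$itype, .data$drug, .data$direction),
    n_datasets = dplyr::n_distinct(.data$pharmaco_dataset),
    datasets = list(sort(unique(.data$pharmaco_dataset))),
    drug_p = list(setNames(.data$drug_p, .data$pharmaco_dataset)),
    .groups = "drop"
  )
}
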