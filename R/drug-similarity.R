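#' Shared-partner similarity test for a drug pair
#'
#' Two drugs are called similar when the overlap of their partner-gene sets
#' exceeds what a hypergeometric draw from the partner universe would give:
#' `p = P(X >= |A n B|)` drawing `|B|` genes from the universe with `|A|`
#' successes.
#'
#' @param partners_a,partners_b Partner-gene sets of the two drugs.
#' @param universe Partner-gene universe (all partner genes in the relevant
#'   network); both sets must be subsets of it.
#' @param alpha Similarity threshold on the p-value (default 0.05).
#' @return One-row tibble: `overlap`, `p`, `similar`.
#' @export
shared_partner_test <- function(partners_a, partners_b, universe, alpha = 0.05) {
  if (length(universe) == 0) abort("shared_partner_test: empty universe")
  partners_a <- unique(partners_a); partners_b <- unique(partners_b)
  if (!all(partners_a %in% universe) || !all(partners_b %in% universe)) {
    abort("shared_partner_test: partner sets must lie in the universe")
  }
  k <- length(intersect(partners_a, partners_b))
  p <- hypergeom_tail(k, length(partners_a), length(partners_b), length(universe))
  tibble::tibble(overlap = k, p = p, similar = p < alpha)
}

#' Jaccard similarity of two ATC code sets
#'
#' @param codes_a,codes_b Non-empty character vectors of ATC codes.
#' @param truncate Optional number of leading characters to compare (to
#'   study ATC level effects); `NULL` compares full codes.
#' @return |intersection| / |union|, in [0, 1]; `NA` with a warning when a
#'   set is empty (such pairs are excluded from group comparisons).
#' @export
atc_jaccard <- function(codes_a, codes_b, truncate = NULL) {
  if (length(codes_a) == 0 || length(codes_b) == 0) {
    warn("atc_jaccard: empty code set, similarity undefined")
    return(NA_real_)
  }
  if (!is.null(truncate)) {
    codes_a <- substr(codes_a, 1, truncate)
    codes_b <- substr(codes_b, 1, truncate)
  }
  codes_a <- unique(codes_a); codes_b <- unique(codes_b)
  length(intersect(codes_a, codes_b)) / length(union(codes_a, codes_b))
}

#' Compare similarity scores between similar and other drug pairs
#'
#' Welch t test (two-sided) on ATC Jaccard or externally supplied GO
#' semantic-similarity scores.
#'
#' @param similar_scores,other_scores Numeric score vectors (each >= 2
#'   non-missing values); `NA` (undefined similarity) is dropped.
#' @return One-row `crgi_test` tibble.
#' @export
compare_groups <- function(similar_scores, other_scores) {
  two_sample_t(similar_scores[!is.na(similar_scores)],
               other_scores[!is.na(other_scores)])
}

#' Drug-pair similarity table for an interaction network
#'
#' Builds all unordered drug pairs in the records, tests shared partners
#' against the network's partner universe, and annotates each pair with the
#' ATC Jaccard similarity where codes are available.
#'
#' @param records Drug-interaction records (columns `drug`, `partner`).
#' @param atc_codes Optional named list mapping drug to ATC codes.
#' @param alpha Similarity threshold (default 0.05).
#' @param truncate Passed to [atc_jaccard()].
#' @return Tibble: drug_a, drug_b, overlap, p, similar, atc_jaccard.
#' @export
drug_pair_table <- function(records, atc_codes = NULL, alpha = 0.05,
                            truncate = NULL) {
  partner_sets <- lapply(split(records$partner, records$drug), unique)
  drugs <- sort(names(partner_sets))
  universe <- unique(records$partner)
  if (length(drugs) < 2) {
    return(tibble::tibble(drug_a = character(0), drug_b = character(0),
                          overlap = integer(0), p = numeric(0),
                          similar = logical(0), atc_jaccard = numeric(0)))
  }
  combos <- utils::combn(drugs, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    res <- shared_partner_test(partner_sets[[a]], partner_sets[[b]],
                               universe, alpha)
    jac <- if (!is.null(atc_codes) && !is.null(atc_codes[[a]]) &&
               !is.null(atc_codes[[b]])) {
      atc_jaccard(atc_codes[[a]], atc_codes[[b]], truncate)
    } else NA_real_
    dplyr::mutate(res, drug_a = a, drug_b = b, .before = 1) |>
      dplyr::mutate(atc_jaccard = jac)
  })
}
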