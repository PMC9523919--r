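#' Orient a screen so that higher scores mean more viable
#'
#' CERES-style screens publish essentiality (lower = more viable knockout
#' effect is reversed), so `"low_is_viable"` matrices are negated and the
#' flag flipped. The operation is idempotent on `"high_is_viable"` screens.
#'
#' @param screen A [screen_dataset()].
#' @return The screen with `orientation == "high_is_viable"`.
#' @export
orient_to_viability <- function(screen) {
  stopifnot(inherits(screen, "screen_dataset"))
  if (screen$orientation == "low_is_viable") {
    screen$scores <- -screen$scores
    screen$orientation <- "high_is_viable"
  }
  screen
}

#' Tissues with enough cell lines to test
#'
#' Only tissue types with more than three cell lines enter the analysis, so
#' the default minimum is 4.
#'
#' @param screen A [screen_dataset()].
#' @param min_lines Minimum cell-line count per tissue (default 4).
#' @return Character vector of eligible tissue labels.
#' @export
eligible_tissues <- function(screen, min_lines = 4) {
  counts <- table(screen$lineages$tissue)
  names(counts)[counts >= min_lines]
}

# One-sided rank-sum p-values for mutant-vs-wild-type target scores.
# Returns list(p_lethal, p_viable, n_mut, n_wt, tested, reason).
pair_test_core <- function(target_scores, mut_lines, min_group) {
  mut <- target_scores[names(target_scores) %in% mut_lines]
  wt <- target_scores[!(names(target_scores) %in% mut_lines)]
  mut <- mut[!is.na(mut)]; wt <- wt[!is.na(wt)]
  if (length(mut) < min_group || length(wt) < min_group) {
    return(list(p_lethal = NA_real_, p_viable = NA_real_,
                n_mut = length(mut), n_wt = length(wt),
                tested = FALSE, reason = "group_below_min"))
  }
  list(p_lethal = rank_sum_core(mut, wt, "less")$p_value,
       p_viable = rank_sum_core(mut, wt, "greater")$p_value,
       n_mut = length(mut), n_wt = length(wt),
       tested = TRUE, reason = NA_character_)
}

#' Test one target/partner pair in one tissue of one screen
#'
#' Within the tissue, the target's viability scores are split by partner
#' alteration status. `p_lethal` tests the alternative "mutant group lower"
#' (synthetic lethality), `p_viable` "mutant group higher" (synthetic
#' viability). Pairs whose mutant or wild-type group falls below
#' `min_group` are flagged untested rather than given p = 1.
#'
#' @param screen A [screen_dataset()], oriented to viability.
#' @param mutations A [mutation_catalog()] over the screen's cell lines.
#' @param tissue Tissue label.
#' @param target Gene whose knockout/knockdown scores are compared.
#' @param partner Gene whose alteration status defines the groups.
#' @param min_group Minimum mutant and wild-type group size (default 3).
#' @return One-row tibble: target, partner, tissue, screen, n_mut, n_wt,
#'   p_lethal, p_viable, tested, reason.
#' @export
test_pair <- function(screen, mutations, tissue, target, partner, min_group = 3) {
  screen <- orient_to_viability(screen)
  lines <- screen$lineages$cell_line[screen$lineages$tissue == tissue]
  row <- tibble::tibble(target = target, partner = partner, tissue = tissue,
                        screen = screen$name)
  if (!target %in% rownames(screen$scores)) {
    return(dplyr::mutate(row, n_mut = NA_integer_, n_wt = NA_integer_,
                         p_lethal = NA_real_, p_viable = NA_real_,
                         tested = FALSE, reason = "target_not_scored"))
  }
  scores <- screen$scores[target, lines]
  res <- pair_test_core(scores, altered_samples(mutations, partner), min_group)
  dplyr::mutate(row, n_mut = res$n_mut, n_wt = res$n_wt,
                p_lethal = res$p_lethal, p_viable = res$p_viable,
                tested = res$tested, reason = res$reason)
}

#' Scan screens for candidate synthetic-lethal/viable pairs
#'
#' Tests every requested (target, partner) pair, in every eligible tissue of
#' every screen, where at least one side is a chromatin regulator. A pair is
#' a CSL candidate in a screen when `p_lethal < alpha` and a CSV candidate
#' when `p_viable < alpha`.
#'
#' @param screens List of [screen_dataset()]s.
#' @param mutation_catalogs Named list of [mutation_catalog()]s, one per
#'   screen (names matching screen names), or a single catalog shared by all
#'   screens.
#' @param cr_genes Character vector of chromatin-regulator gene symbols.
#' @param pairs Optional tibble with columns `target`, `partner` restricting
#'   the scan; by default all `targets` x `partners` combinations are used.
#' @param targets,partners Gene universes used when `pairs` is not given;
#'   `targets` defaults to genes scored in each screen, `partners` to genes
#'   with at least one altering mutation.
#' @param alpha Per-screen nominal significance level (default 0.05). The
#'   multi-screen design deliberately filters on nominal p here; optional BH
#'   adjustment per tissue is available via `adjust`.
#' @param min_lines Tissue eligibility threshold (default 4).
#' @param min_group Per-test minimum group size (default 3).
#' @param keep_all Keep rows that are not candidates (default FALSE).
#' @param adjust If TRUE, BH-adjust p-values within each screen x tissue
#'   before applying `alpha`.
#' @return Tibble of per-(screen, tissue, pair) tests with `direction`
#'   (`"CSL"`, `"CSV"` or `NA`) and `candidate` columns.
#' @export
scan_candidates <- function(screens, mutation_catalogs, cr_genes,
                            pairs = NULL, targets = NULL, partners = NULL,
                            alpha = 0.05, min_lines = 4, min_group = 3,
                            keep_all = FALSE, adjust = FALSE) {
  if (inherits(mutation_catalogs, "mutation_catalog")) {
    mutation_catalogs <- setNames(
      rep(list(mutation_catalogs), length(screens)),
      vapply(screens, `[[`, character(1), "name"))
  }
  out <- purrr::map_dfr(screens, function(screen) {
    screen <- orient_to_viability(screen)
    muts <- mutation_catalogs[[screen$name]]
    if (is.null(muts)) abort(paste0("no mutation catalog for screen ", screen$name))
    tissues <- eligible_tissues(screen, min_lines)
    if (length(tissues) == 0) {
      warn(paste0("screen ", screen$name, ": no eligible tissue"))
      return(tibble::tibble())
    }
    scan_pairs <- pairs
    if (is.null(scan_pairs)) {
      tg <- targets %||% rownames(screen$scores)
      pt <- partners %||% unique(muts$gene[muts$altering])
      scan_pairs <- tidyr::expand_grid(target = tg, partner = pt)
    }
    scan_pairs <- dplyr::filter(scan_pairs,
                                .data$target %in% cr_genes | .data$partner %in% cr_genes,
                                .data$target != .data$partner,
                                .data$target %in% rownames(screen$scores))
    purrr::map_dfr(tissues, function(tis) {
      lines <- screen$lineages$cell_line[screen$lineages$tissue == tis]
      score_sub <- screen$scores[unique(scan_pairs$target), lines, drop = FALSE]
      mut_sets <- split(muts$sample[muts$altering], muts$gene[muts$altering])
      m <- nrow(scan_pairs)
      n_mut <- integer(m); n_wt <- integer(m)
      p_lethal <- numeric(m); p_viable <- numeric(m)
      tested <- logical(m); reason <- character(m)
      tg <- scan_pairs$target; pt <- scan_pairs$partner
      for (j in seq_len(m)) {
        core <- pair_test_core(score_sub[tg[[j]], ],
                               mut_sets[[pt[[j]]]] %||% character(0), min_group)
        n_mut[j] <- core$n_mut; n_wt[j] <- core$n_wt
        p_lethal[j] <- core$p_lethal; p_viable[j] <- core$p_viable
        tested[j] <- core$tested; reason[j] <- core$reason %||% NA_character_
      }
      tibble::tibble(tissue = tis, screen = screen$name,
                     target = tg, partner = pt, n_mut = n_mut, n_wt = n_wt,
                     p_lethal = p_lethal, p_viable = p_viable,
                     tested = tested, reason = reason)
    })
  })
  if (nrow(out) == 0) return(out)
  if (adjust) {
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$screen, .data$tissue),
      p_lethal = ifelse(.data$tested, bh_adjust_allow_na(.data$p_lethal), NA_real_),
      p_viable = ifelse(.data$tested, bh_adjust_allow_na(.data$p_viable), NA_real_)
    )
    out <- dplyr::ungroup(out)
  }
  out <- dplyr::mutate(
    out,
    direction = dplyr::case_when(
      .data$tested & .data$p_lethal < alpha & .data$p_viable < alpha ~ "conflict",
      .data$tested & .data$p_lethal < alpha ~ "CSL",
      .data$tested & .data$p_viable < alpha ~ "CSV",
      TRUE ~ NA_character_
    ),
    candidate = !is.na(.data$direction)
  )
  if (!keep_all) out <- dplyr::filter(out, .data$candidate | !.data$tested)
  out
}

bh_adjust_allow_na <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bh_adjust(p[ok])
  out
}

#' Multi-screen consensus of candidate interactions
#'
#' A (target, partner, tissue) pair becomes a consensus interaction in a
#' direction when it is nominally significant in that direction in at least
#' `min_support` screens and the Fisher combination of its directional
#' p-values — taken from *every* screen in which the pair was testable, not
#' only the supporting ones — is below `alpha_combined`. A pair significant
#' as CSL in one screen and CSV in another is emitted with
#' `conflict = TRUE` and is not a consensus record.
#'
#' @param candidates Output of [scan_candidates()] (rows from all screens;
#'   must include untested/non-candidate rows or at least all tested
#'   directional p-values for the pairs of interest, i.e. run with
#'   `keep_all = TRUE` for faithful combination).
#' @param min_support Minimum number of nominally significant screens
#'   (default 2).
#' @param alpha Per-screen nominal level used for support (default 0.05).
#' @param alpha_combined Threshold on the combined p (default 0.05).
#' @return Tibble of interaction records: target, partner, tissue, itype,
#'   combined_p, n_support, support (list of screen names), per_dataset_p
#'   (named list), n_mut/n_wt (first supporting screen), conflict.
#' @export
consensus <- function(candidates, min_support = 2, alpha = 0.05,
                      alpha_combined = 0.05) {
  tested <- dplyr::filter(candidates, .data$tested)
  if (nrow(tested) == 0) return(empty_interactions())
  grouped <- dplyr::group_split(
    dplyr::group_by(tested, .data$target, .data$partner, .data$tissue))
  recs <- purrr::map_dfr(grouped, function(g) {
    sup_csl <- g$screen[g$p_lethal < alpha]
    sup_csv <- g$screen[g$p_viable < alpha]
    conflict <- length(sup_csl) > 0 && length(sup_csv) > 0
    purrr::map_dfr(c("CSL", "CSV"), function(itype) {
      sup <- if (itype == "CSL") sup_csl else sup_csv
      if (length(sup) < min_support && !(conflict && length(sup) > 0)) {
        return(tibble::tibble())
      }
      pvec <- setNames(if (itype == "CSL") g$p_lethal else g$p_viable, g$screen)
      comb <- fisher_combine(unname(pvec))
      tibble::tibble(
        target = g$target[[1]], partner = g$partner[[1]], tissue = g$tissue[[1]],
        itype = itype, combined_p = comb,
        n_support = length(sup), support = list(sort(sup)),
        per_dataset_p = list(pvec),
        n_mut = g$n_mut[match(sup[1], g$screen)],
        n_wt = g$n_wt[match(sup[1], g$screen)],
        conflict = conflict
      )
    })
  })
  if (nrow(recs) == 0) return(empty_interactions())
  dplyr::filter(recs,
                .data$conflict |
                  (.data$n_support >= min_support & .data$combined_p < alpha_combined))
}

empty_interactions <- function() {
  tibble::tibble(target = character(0), partner = character(0),
                 tissue = character(0), itype = character(0),
                 combined_p = numeric(0), n_support = integer(0),
                 support = list(), per_dataset_p = list(),
                 n_mut = integer(0), n_wt = integer(0), conflict = logical(0))
}

#' Consensus records only (conflicts removed)
#' @param records Output of [consensus()].
#' @return The records with `conflict == FALSE`.
#' @export
consensus_records <- function(records) {
  dplyr::filter(records, !.data$conflict)
}
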