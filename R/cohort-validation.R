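#' Pairwise correlation of interaction genes in a cohort assay
#'
#' Pearson correlation across samples for each (target, partner) pair in an
#' expression or methylation matrix, classified as `"positive"` (r > 0,
#' p < alpha), `"negative"` (r < 0, p < alpha) or `"none"`.
#'
#' @param mat Gene-by-sample numeric matrix.
#' @param pairs Tibble with columns `target`, `partner`.
#' @param kind Label recorded in the output (e.g. "expression").
#' @param alpha Significance level (default 0.05).
#' @return Tibble: target, partner, kind, r, p_value, n, class, reason
#'   (`NA` unless the pair was skipped).
#' @export
pairwise_correlation <- function(mat, pairs, kind = "expression", alpha = 0.05) {
  purrr::pmap_dfr(pairs[, c("target", "partner")], function(target, partner) {
    row <- tibble::tibble(target = target, partner = partner, kind = kind)
    if (!target %in% rownames(mat) || !partner %in% rownames(mat)) {
      return(dplyr::mutate(row, r = NA_real_, p_value = NA_real_,
                           n = NA_integer_, class = NA_character_,
                           reason = "gene_not_measured"))
    }
    if (target == partner) {
      return(dplyr::mutate(row, r = 1, p_value = P_FLOOR,
                           n = ncol(mat), class = "positive",
                           reason = NA_character_))
    }
    res <- pearson_cor(mat[target, ], mat[partner, ])
    cls <- if (res$degenerate || res$p_value >= alpha) "none"
           else if (res$r > 0) "positive" else "negative"
    dplyr::mutate(row, r = res$r, p_value = res$p_value, n = res$n,
                  class = cls,
                  reason = ifelse(res$degenerate, "zero_variance", NA_character_))
  })
}

#' Split partner-mutant patients by the target's median expression
#'
#' Only interactions whose partner mutation frequency in the cohort exceeds
#' `min_mut_freq` are analysed; the partner-mutant patients are then split
#' at the target's median expression *among those patients*, with ties at
#' the median going to the low group (low expression mimics drug
#' inhibition, so the low group is the reference everywhere).
#'
#' @param cohort A [cohort()].
#' @param target,partner Interaction genes.
#' @param min_mut_freq Minimum partner mutation frequency (default 0.10,
#'   strictly exceeded).
#' @return An object of class `crgi_split` with `low`, `high` sample sets,
#'   or `NULL` (with attribute) when skipped; check with [split_ok()].
#' @export
split_by_target_median <- function(cohort, target, partner, min_mut_freq = 0.10) {
  samples <- cohort_samples(cohort)
  if (!target %in% rownames(cohort$expression)) {
    return(skipped_split(target, partner, "target_not_measured"))
  }
  mut <- intersect(altered_samples(cohort$mutations, partner), samples)
  freq <- length(mut) / length(samples)
  if (freq <= min_mut_freq) {
    return(skipped_split(target, partner, "mutation_frequency_below_threshold"))
  }
  expr <- cohort$expression[target, mut]
  med <- median(expr)
  low <- names(expr)[expr <= med]
  high <- names(expr)[expr > med]
  structure(list(target = target, partner = partner,
                 low = low, high = high, median = med,
                 mutation_frequency = freq,
                 degenerate = length(high) == 0 || length(low) == 0,
                 reason = NA_character_),
            class = "crgi_split")
}

skipped_split <- function(target, partner, reason) {
  structure(list(target = target, partner = partner,
                 low = character(0), high = character(0),
                 median = NA_real_, mutation_frequency = NA_real_,
                 degenerate = TRUE, reason = reason),
            class = "crgi_split")
}

#' Construct a group split from explicit sample sets
#'
#' For running [differential_features()] or [score_shift_test()] on groups
#' defined outside the target-median rule (e.g. module carriers).
#'
#' @param low,high Disjoint sample identifier vectors.
#' @param target,partner Optional labels carried into reports.
#' @return A `crgi_split`.
#' @export
manual_split <- function(low, high, target = NA_character_,
                         partner = NA_character_) {
  if (length(intersect(low, high)) > 0) abort("manual_split: groups overlap")
  structure(list(target = target, partner = partner,
                 low = low, high = high, median = NA_real_,
                 mutation_frequency = NA_real_,
                 degenerate = length(low) == 0 || length(high) == 0,
                 reason = NA_character_),
            class = "crgi_split")
}

#' Was a group split usable?
#' @param split A `crgi_split`.
#' @return TRUE when both groups are non-empty and the split was not skipped.
#' @export
split_ok <- function(split) {
  is.na(split$reason) && !split$degenerate
}

#' @export
print.crgi_split <- function(x, ...) {
  cat("<crgi_split> target ", x$target, " | partner ", x$partner, "\n",
      "  low: ", length(x$low), ", high: ", length(x$high),
      if (!is.na(x$reason)) paste0("  [skipped: ", x$reason, "]") else "",
      "\n", sep = "")
  invisible(x)
}

#' Directional differential features between split groups
#'
#' For every feature (gene, methylation probe, accessibility peak) a
#' one-sided rank-sum test is run in both directions — "up" meaning higher
#' in the low-expression (reference) group — and BH adjustment is applied
#' across features separately per direction. Features with adjusted
#' p < `fdr` are reported.
#'
#' @param mat Feature-by-sample numeric matrix.
#' @param split A `crgi_split` from [split_by_target_median()].
#' @param fdr FDR threshold (default 0.1).
#' @return List with `up`, `down` (character vectors of features) and
#'   `table` (per-feature p-values and adjusted p-values).
#' @export
differential_features <- function(mat, split, fdr = 0.1) {
  low <- intersect(split$low, colnames(mat))
  high <- intersect(split$high, colnames(mat))
  if (length(low) < 3 || length(high) < 3) {
    abort("differential_features: group with fewer than 3 samples")
  }
  features <- rownames(mat)
  p_up <- numeric(length(features))
  p_down <- numeric(length(features))
  for (i in seq_along(features)) {
    x <- mat[i, low]; y <- mat[i, high]
    p_up[i] <- rank_sum_core(x, y, "greater")$p_value
    p_down[i] <- rank_sum_core(x, y, "less")$p_value
  }
  q_up <- bh_adjust(p_up)
  q_down <- bh_adjust(p_down)
  tbl <- tibble::tibble(feature = features, p_up = p_up, q_up = q_up,
                        p_down = p_down, q_down = q_down)
  list(up = features[q_up < fdr], down = features[q_down < fdr], table = tbl)
}

#' Shift of a per-sample score between split groups
#'
#' One-sided rank-sum in both directions; the smaller-p direction is
#' reported ("up" = higher in the low-expression reference group).
#'
#' @param scores Named numeric vector (per-sample score, e.g. an HRD
#'   component or an immune-cell fraction).
#' @param split A `crgi_split`.
#' @param alpha Significance level (default 0.05).
#' @return One-row tibble: direction, p_value, significant, degenerate.
#' @export
score_shift_test <- function(scores, split, alpha = 0.05) {
  x <- scores[intersect(split$low, names(scores))]
  y <- scores[intersect(split$high, names(scores))]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    return(tibble::tibble(direction = NA_character_, p_value = NA_real_,
                          significant = FALSE, degenerate = TRUE))
  }
  up <- rank_sum_test(x, y, "greater")
  down <- rank_sum_test(x, y, "less")
  if (up$degenerate) {
    return(tibble::tibble(direction = NA_character_, p_value = 1,
                          significant = FALSE, degenerate = TRUE))
  }
  if (up$p_value <= down$p_value) {
    tibble::tibble(direction = "up", p_value = up$p_value,
                   significant = up$p_value < alpha, degenerate = FALSE)
  } else {
    tibble::tibble(direction = "down", p_value = down$p_value,
                   significant = down$p_value < alpha, degenerate = FALSE)
  }
}

#' Hypergeometric pathway enrichment
#'
#' Upper-tail hypergeometric test of the query set's overlap with each
#' pathway, BH-adjusted across pathways.
#'
#' @param genes Query gene set (subset of `universe`).
#' @param pathways Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Background gene universe.
#' @param fdr FDR threshold for the `significant` flag (default 0.1).
#' @return Tibble sorted by p: pathway, overlap, pathway_size, p, q,
#'   significant.
#' @export
pathway_enrichment <- function(genes, pathways, universe, fdr = 0.1) {
  if (length(pathways) == 0) abort("pathway_enrichment: empty pathway collection")
  genes <- intersect(unique(genes), universe)
  N <- length(unique(universe))
  n <- length(genes)
  rows <- purrr::imap_dfr(pathways, function(set, nm) {
    set <- intersect(unique(set), universe)
    k <- length(intersect(genes, set))
    p <- if (length(set) == 0) 1 else hypergeom_tail(k, length(set), n, N)
    tibble::tibble(pathway = nm, overlap = k, pathway_size = length(set), p = p)
  })
  rows$q <- bh_adjust(rows$p)
  rows$significant <- rows$q < fdr
  dplyr::arrange(rows, .data$p, .data$pathway)
}

#' Full cohort validation report for a set of interactions
#'
#' For each interaction: expression and methylation correlation of the gene
#' pair, the partner-mutant split by target median expression, counts of
#' up/down differential genes (expression and, when present, methylation
#' and accessibility features), and score-shift tests for each per-sample
#' score row.
#'
#' @param cohort A [cohort()].
#' @param interactions Interaction records (target, partner, itype).
#' @param min_mut_freq Partner mutation frequency threshold (default 0.10).
#' @param fdr FDR for differential features (default 0.1).
#' @param alpha Level for correlations and score shifts (default 0.05).
#' @return Tibble, one row per interaction, with correlation classes,
#'   differential counts and a `score_shifts` list-column.
#' @export
cohort_validation_report <- function(cohort, interactions, min_mut_freq = 0.10,
                                     fdr = 0.1, alpha = 0.05) {
  purrr::pmap_dfr(interactions[, c("target", "partner", "itype")],
                  function(target, partner, itype) {
    row <- tibble::tibble(target = target, partner = partner, itype = itype)
    expr_cor <- pairwise_correlation(cohort$expression,
                                     tibble::tibble(target = target, partner = partner),
                                     "expression", alpha)
    meth_cor <- if (!is.null(cohort$methylation)) {
      pairwise_correlation(cohort$methylation,
                           tibble::tibble(target = target, partner = partner),
                           "methylation", alpha)
    } else NULL
    split <- split_by_target_median(cohort, target, partner, min_mut_freq)
    row <- dplyr::mutate(
      row,
      expr_class = expr_cor$class, expr_r = expr_cor$r,
      meth_class = if (is.null(meth_cor)) NA_character_ else meth_cor$class,
      meth_r = if (is.null(meth_cor)) NA_real_ else meth_cor$r,
      split_reason = split$reason, n_low = length(split$low),
      n_high = length(split$high)
    )
    if (!split_ok(split) ||
        length(split$low) < 3 || length(split$high) < 3) {
      return(dplyr::mutate(row, n_expr_up = NA_integer_, n_expr_down = NA_integer_,
                           n_meth_up = NA_integer_, n_meth_down = NA_integer_,
                           n_feat_up = NA_integer_, n_feat_down = NA_integer_,
                           score_shifts = list(NULL)))
    }
    de <- differential_features(cohort$expression, split, fdr)
    dm <- if (!is.null(cohort$methylation))
      differential_features(cohort$methylation, split, fdr) else NULL
    dfm <- if (!is.null(cohort$feature_matrix))
      differential_features(cohort$feature_matrix, split, fdr) else NULL
    shifts <- if (!is.null(cohort$sample_scores)) {
      purrr::map_dfr(rownames(cohort$sample_scores), function(sc) {
        dplyr::mutate(score_shift_test(cohort$sample_scores[sc, ], split, alpha),
                      score = sc, .before = 1)
      })
    } else NULL
    dplyr::mutate(row,
                  n_expr_up = length(de$up), n_expr_down = length(de$down),
                  n_meth_up = if (is.null(dm)) NA_integer_ else length(dm$up),
                  n_meth_down = if (is.null(dm)) NA_integer_ else length(dm$down),
                  n_feat_up = if (is.null(dfm)) NA_integer_ else length(dfm$up),
                  n_feat_down = if (is.null(dfm)) NA_integer_ else length(dfm$down),
                  score_shifts = list(shifts))
  })
}
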