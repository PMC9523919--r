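#' Activation rule for interactions in patients
#'
#' An interaction is "activated" in a patient when the partner carries an
#' altering mutation AND the target's expression lies on the specified side
#' of the cohort-wide median (default: below, i.e. `<=` the median — low
#' expression mimicking drug inhibition of the target). The expression side
#' is configurable because the literature leaves the predicate implicit;
#' every report records the rule used.
#'
#' @param side `"below"` or `"above"` the cohort median.
#' @return An object of class `activation_rule`.
#' @export
activation_rule <- function(side = c("below", "above")) {
  structure(list(side = match.arg(side)), class = "activation_rule")
}

rule_expression_side <- function(cohort, target, rule) {
  expr <- cohort$expression[target, ]
  med <- median(expr, na.rm = TRUE)
  if (rule$side == "below") names(expr)[!is.na(expr) & expr <= med]
  else names(expr)[!is.na(expr) & expr > med]
}

activated_samples <- function(cohort, target, partner, rule) {
  if (!target %in% rownames(cohort$expression)) return(character(0))
  intersect(intersect(altered_samples(cohort$mutations, partner),
                      cohort_samples(cohort)),
            rule_expression_side(cohort, target, rule))
}

#' Log-rank survival split for a single interaction
#'
#' Among partner-mutant patients, compares survival of the target-low and
#' target-high groups (split at the target's median expression among those
#' patients, ties low).
#'
#' @param cohort A [cohort()].
#' @param target,partner Interaction genes.
#' @param min_mut_freq Partner mutation frequency threshold (default 0; the
#'   cohort-validation default of 0.10 can be passed explicitly).
#' @return List of class `crgi_surv`: `test` (log-rank `crgi_test` row),
#'   `km` (per-group KM curves), `groups` (sample/group tibble),
#'   `degenerate`, `reason`.
#' @export
single_pair_survival <- function(cohort, target, partner, min_mut_freq = 0) {
  split <- split_by_target_median(cohort, target, partner, min_mut_freq)
  if (!split_ok(split)) {
    return(structure(list(test = NULL, km = NULL, groups = NULL,
                          degenerate = TRUE, reason = split$reason %||% "single_sided_split"),
                     class = "crgi_surv"))
  }
  groups <- tibble::tibble(
    sample = c(split$low, split$high),
    group = rep(c("target_low", "target_high"),
                c(length(split$low), length(split$high)))
  )
  compare_survival(cohort, groups)
}

#' Count activated interactions per patient
#'
#' @param cohort A [cohort()].
#' @param interactions Interaction records (target, partner).
#' @param rule An [activation_rule()].
#' @return Tibble `sample`, `count` covering every cohort sample.
#' @export
count_activated <- function(cohort, interactions, rule = activation_rule()) {
  samples <- cohort_samples(cohort)
  counts <- setNames(integer(length(samples)), samples)
  if (nrow(interactions) > 0) {
    for (i in seq_len(nrow(interactions))) {
      act <- activated_samples(cohort, interactions$target[[i]],
                               interactions$partner[[i]], rule)
      counts[act] <- counts[act] + 1L
    }
  }
  tibble::tibble(sample = samples, count = unname(counts))
}

#' Burden groups from per-patient activation counts
#'
#' Patients with no activated interaction form the `"none"` group; carriers
#' are split at the median carrier count, ties going to `"fewer"`.
#'
#' @param counts Tibble from [count_activated()] (columns sample, count).
#' @return Tibble `sample`, `count`, `group` (factor none/fewer/more); the
#'   attribute `"degenerate"` is TRUE when there are no carriers.
#' @export
burden_groups <- function(counts) {
  carriers <- counts$count[counts$count > 0]
  if (length(carriers) == 0) {
    out <- dplyr::mutate(counts, group = factor("none", levels = c("none", "fewer", "more")))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  med <- median(carriers)
  out <- dplyr::mutate(
    counts,
    group = factor(dplyr::case_when(
      .data$count == 0 ~ "none",
      .data$count <= med ~ "fewer",
      TRUE ~ "more"
    ), levels = c("none", "fewer", "more"))
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' Build a drug-target module of interactions
#'
#' The union of partner genes whose interactions share one target (and
#' tissue), used to raise biomarker coverage; the interaction type must be
#' homogeneous.
#'
#' @param interactions Interaction records (target, partner, tissue, itype;
#'   `drug` optional).
#' @param target Module target gene.
#' @param tissue Tissue label.
#' @return List of class `module_definition`: target, tissue, partners,
#'   drugs, itype.
#' @export
build_module <- function(interactions, target, tissue) {
  sel <- dplyr::filter(interactions, .data$target == !!target,
                       .data$tissue == !!tissue)
  if (nrow(sel) == 0) abort("build_module: no interaction with that target and tissue")
  itypes <- unique(sel$itype)
  if (length(itypes) > 1) abort("build_module: mixed CSL/CSV interactions")
  structure(list(target = target, tissue = tissue,
                 partners = sort(unique(sel$partner)),
                 drugs = if ("drug" %in% names(sel)) sort(unique(sel$drug)) else character(0),
                 itype = itypes),
            class = "module_definition")
}

#' @export
print.module_definition <- function(x, ...) {
  cat("<module_definition> ", x$itype, " module of ", x$target,
      " (", x$tissue, ")\n",
      "  partners: ", paste(x$partners, collapse = ", "), "\n",
      "  drugs: ", paste(x$drugs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Split a cohort by module carrier status
#'
#' Synthetic-viable modules compare carriers of at least one activated
#' module interaction against all other patients. Synthetic-lethal modules
#' restrict to patients mutated in at least one module partner and split
#' them by the target's median expression (among those patients).
#'
#' @param cohort A [cohort()].
#' @param module A [build_module()] result.
#' @param rule An [activation_rule()] (used for the CSV-style split).
#' @param style `"auto"` picks by module itype; `"carrier"` or
#'   `"expression"` force a style.
#' @return Tibble `sample`, `group`; attribute `"degenerate"` is TRUE when
#'   a group is empty.
#' @export
module_carrier_split <- function(cohort, module, rule = activation_rule(),
                                 style = c("auto", "carrier", "expression")) {
  style <- match.arg(style)
  if (style == "auto") style <- if (module$itype == "CSV") "carrier" else "expression"
  samples <- cohort_samples(cohort)
  if (style == "carrier") {
    activated <- unique(unlist(lapply(module$partners, function(p) {
      activated_samples(cohort, module$target, p, rule)
    })))
    out <- tibble::tibble(
      sample = samples,
      group = ifelse(samples %in% activated, "carrier", "non_carrier")
    )
    attr(out, "degenerate") <- length(activated) == 0 || length(activated) == length(samples)
    return(out)
  }
  mutants <- intersect(
    unique(unlist(lapply(module$partners, altered_samples, mutations = cohort$mutations))),
    samples)
  if (length(mutants) == 0 || !module$target %in% rownames(cohort$expression)) {
    out <- tibble::tibble(sample = character(0), group = character(0))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  expr <- cohort$expression[module$target, mutants]
  med <- median(expr, na.rm = TRUE)
  out <- tibble::tibble(
    sample = mutants,
    group = ifelse(expr <= med, "target_low", "target_high")
  )
  attr(out, "degenerate") <- length(unique(out$group)) < 2
  out
}

#' Compare survival across patient groups
#'
#' Log-rank test over all groups plus per-group Kaplan-Meier curves.
#'
#' @param cohort A [cohort()].
#' @param groups Tibble `sample`, `group` (samples must have survival
#'   records; others are dropped).
#' @param pairwise Also compute all pairwise log-rank tests (default FALSE).
#' @return List of class `crgi_surv`: `test`, `km` (tibble with a `group`
#'   column), `groups`, `pairwise` (optional), `degenerate`, `reason`.
#' @export
compare_survival <- function(cohort, groups, pairwise = FALSE) {
  data <- dplyr::inner_join(cohort$survival, groups, by = "sample")
  sizes <- table(data$group)
  if (length(sizes) < 2 || any(sizes == 0)) {
    return(structure(list(test = NULL, km = NULL, groups = groups,
                          degenerate = TRUE, reason = "fewer_than_two_groups"),
                     class = "crgi_surv"))
  }
  test <- logrank_test(data)
  km <- purrr::map_dfr(split(data, data$group), function(d) {
    dplyr::mutate(km_curve(d$time, d$event), group = d$group[[1]], .before = 1)
  })
  pw <- NULL
  if (pairwise && length(sizes) > 2) {
    combos <- utils::combn(names(sizes), 2)
    pw <- purrr::map_dfr(seq_len(ncol(combos)), function(i) {
      sub <- dplyr::filter(data, .data$group %in% combos[, i])
      dplyr::mutate(logrank_test(sub), group_a = combos[1, i], group_b = combos[2, i])
    })
  }
  structure(list(test = test, km = km, groups = groups, pairwise = pw,
                 degenerate = isTRUE(test$degenerate), reason = NA_character_),
            class = "crgi_surv")
}

#' @export
print.crgi_surv <- function(x, ...) {
  if (is.null(x$test)) {
    cat("<crgi_surv> degenerate (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat("<crgi_surv> log-rank chi-square = ", signif(x$test$statistic, 4),
      " (df ", x$test$df, "), p = ", signif(x$test$p_value, 3), "\n", sep = "")
  invisible(x)
}
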