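default_thresholds <- function() {
  list(alpha = 0.05, alpha_combined = 0.05, min_support = 2,
       fdr = 0.1, min_lines = 4, min_group = 3,
       min_mut_freq = 0.10, n_perm = 1000)
}

#' Load and validate a pipeline configuration
#'
#' @param config Path to a YAML file or a named list. Recognised keys:
#'   `seed` (integer), `bundle_dir` (input bundle; defaults to
#'   `<out_dir>/bundle`), `thresholds` (any of alpha, alpha_combined,
#'   min_support, fdr, min_lines, min_group, min_mut_freq, n_perm) and
#'   `sim` (overrides passed to [sim_config()] by the simulate stage).
#' @param out_dir Output directory, used for the `bundle_dir` default.
#' @return Validated config list with thresholds filled in.
#' @export
load_config <- function(config = list(), out_dir = ".") {
  if (is.character(config)) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  config$seed <- as.integer(config$seed %||% 1L)
  config$bundle_dir <- config$bundle_dir %||% file.path(out_dir, "bundle")
  th <- utils::modifyList(default_thresholds(), config$thresholds %||% list())
  for (nm in c("alpha", "alpha_combined", "fdr", "min_mut_freq")) {
    if (!is.numeric(th[[nm]]) || th[[nm]] <= 0 || th[[nm]] > 1) {
      abort(paste0("invalid threshold ", nm, ": must lie in (0, 1]"))
    }
  }
  for (nm in c("min_lines", "min_group", "min_support", "n_perm")) {
    if (!is.numeric(th[[nm]]) || th[[nm]] < 1) {
      abort(paste0("invalid threshold ", nm, ": must be >= 1"))
    }
  }
  config$thresholds <- th
  config
}

write_manifest <- function(out_dir, stage, config, counts = list()) {
  manifest <- list(
    stage = stage,
    seed = config$seed,
    thresholds = config$thresholds,
    # hash only location-independent fields so identical runs in different
    # directories produce identical manifests
    config_hash = rlang::hash(config[intersect(sort(names(config)),
                                               c("seed", "thresholds", "sim"))]),
    counts = counts
  )
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

read_bundle_screens <- function(bundle_dir) {
  meta <- readr::read_tsv(file.path(bundle_dir, "screens.tsv"),
                          col_types = readr::cols(), progress = FALSE)
  lineages <- readr::read_tsv(file.path(bundle_dir, "lineages.tsv"),
                              col_types = readr::cols(), progress = FALSE)
  screens <- purrr::pmap(meta, function(name, orientation, scores, mutations) {
    screen_dataset(read_matrix(file.path(bundle_dir, scores), "dependency score"),
                   lineages, name, orientation)
  })
  catalogs <- setNames(
    purrr::map(meta$mutations, ~read_mutations(file.path(bundle_dir, .x))),
    meta$name)
  list(screens = screens, mutations = catalogs, lineages = lineages)
}

read_bundle_pharmaco <- function(bundle_dir, lineages) {
  meta <- readr::read_tsv(file.path(bundle_dir, "pharmaco.tsv"),
                          col_types = readr::cols(), progress = FALSE)
  datasets <- purrr::pmap(meta, function(name, metric, responses) {
    drug_response_dataset(read_matrix(file.path(bundle_dir, responses), "response"),
                          lineages, name, metric)
  })
  muts <- read_mutations(file.path(bundle_dir, "pharmaco", "mutations.tsv"))
  list(datasets = datasets, mutations = muts)
}

read_bundle_cohort <- function(bundle_dir) {
  cdir <- file.path(bundle_dir, "cohort")
  cohort(
    expression = read_matrix(file.path(cdir, "expression.tsv"), "expression"),
    survival = readr::read_tsv(file.path(cdir, "survival.tsv"),
                               col_types = readr::cols(), progress = FALSE),
    mutations = read_mutations(file.path(cdir, "mutations.tsv")),
    methylation = read_matrix(file.path(cdir, "methylation.tsv"), "methylation"),
    sample_scores = read_matrix(file.path(cdir, "sample_scores.tsv"), "score")
  )
}

stage_simulate <- function(config, out_dir) {
  sim_args <- config$sim %||% list()
  sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  simulate_bundle(cfg, config$bundle_dir)
  write_manifest(out_dir, "simulate", config,
                 counts = list(n_planted_csl = sum(cfg$planted$itype == "CSL"),
                               n_planted_csv = sum(cfg$planted$itype == "CSV")))
  invisible(config$bundle_dir)
}

stage_screen_gi <- function(config, out_dir) {
  th <- config$thresholds
  bundle <- read_bundle_screens(config$bundle_dir)
  cr_genes <- readr::read_tsv(file.path(config$bundle_dir, "cr_genes.tsv"),
                              col_types = readr::cols(), progress = FALSE)$gene
  drug_map <- drug_target_map(
    read_pairs(file.path(config$bundle_dir, "drug_targets.tsv"),
               c("drug", "target")))
  targets <- unique(drug_map$target)
  cands <- scan_candidates(bundle$screens, bundle$mutations, cr_genes,
                           targets = targets,
                           alpha = th$alpha, min_lines = th$min_lines,
                           min_group = th$min_group, keep_all = TRUE)
  cons <- consensus(cands, min_support = th$min_support, alpha = th$alpha,
                    alpha_combined = th$alpha_combined)
  readr::write_tsv(cands, file.path(out_dir, "candidates.tsv"), na = "",
                   progress = FALSE)
  write_results(cons, file.path(out_dir, "consensus.tsv"),
                metadata = list(seed = config$seed, thresholds = th,
                                screens = vapply(bundle$screens, `[[`,
                                                 character(1), "name")))
  write_manifest(out_dir, "screen_gi", config, counts = list(
    n_tested = sum(cands$tested),
    n_candidate_csl = sum(cands$direction == "CSL", na.rm = TRUE),
    n_candidate_csv = sum(cands$direction == "CSV", na.rm = TRUE),
    n_consensus_csl = sum(cons$itype == "CSL" & !cons$conflict),
    n_consensus_csv = sum(cons$itype == "CSV" & !cons$conflict),
    n_conflict = sum(cons$conflict)
  ))
  invisible(cons)
}

stage_drug_filter <- function(config, out_dir) {
  th <- config$thresholds
  cons <- consensus_records(read_results(file.path(out_dir, "consensus.tsv")))
  lineages <- readr::read_tsv(file.path(config$bundle_dir, "lineages.tsv"),
                              col_types = readr::cols(), progress = FALSE)
  ph <- read_bundle_pharmaco(config$bundle_dir, lineages)
  drug_map <- drug_target_map(
    read_pairs(file.path(config$bundle_dir, "drug_targets.tsv"),
               c("drug", "target")))
  recs <- pharmaco_filter(cons, drug_map, ph$datasets, ph$mutations,
                          min_group = th$min_group, min_lines = th$min_lines,
                          alpha = th$alpha, keep_all = TRUE)
  retained <- dplyr::filter(recs, .data$retained)
  write_results(retained, file.path(out_dir, "drug_records.tsv"),
                metadata = list(seed = config$seed, thresholds = th,
                                datasets = vapply(ph$datasets, `[[`,
                                                  character(1), "name")))
  write_manifest(out_dir, "drug_filter", config, counts = list(
    n_interaction_drug_tests = nrow(recs),
    n_retained = nrow(retained),
    n_csl_drug = sum(retained$itype == "CSL"),
    n_csv_drug = sum(retained$itype == "CSV"),
    n_drugs = length(unique(retained$drug))
  ))
  invisible(retained)
}

stage_network <- function(config, out_dir) {
  th <- config$thresholds
  recs <- read_results(file.path(out_dir, "drug_records.tsv"))
  net <- build_network(recs)
  ppi <- ppi_graph(read_pairs(file.path(config$bundle_dir, "ppi.tsv")))
  cr_genes <- readr::read_tsv(file.path(config$bundle_dir, "cr_genes.tsv"),
                              col_types = readr::cols(), progress = FALSE)$gene
  cancer_genes <- readr::read_tsv(file.path(config$bundle_dir, "cancer_genes.tsv"),
                                  col_types = readr::cols(), progress = FALSE)$gene
  readr::write_tsv(net$gene_edges, file.path(out_dir, "network_gene_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(net$drug_edges, file.path(out_dir, "network_drug_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(degree_table(net), file.path(out_dir, "network_degrees.tsv"),
                   progress = FALSE)
  overlap <- if (nrow(net$gene_edges) > 0) {
    ppi_overlap_test(net, ppi, n_perm = th$n_perm, seed = config$seed)
  } else NULL
  network_crs <- intersect(net$genes, cr_genes)
  enr <- if (length(network_crs) > 0) {
    cancer_gene_enrichment(network_crs, cr_genes, cancer_genes)
  } else NULL
  summary <- list(
    n_genes = length(net$genes), n_drugs = length(net$drugs),
    n_gene_edges = nrow(net$gene_edges), n_drug_edges = nrow(net$drug_edges),
    ppi_observed_rate = if (!is.null(overlap)) overlap$observed_rate,
    ppi_empirical_p = if (!is.null(overlap)) overlap$empirical_p,
    cancer_enrichment_p = if (!is.null(enr)) enr$p_value
  )
  jsonlite::write_json(summary, file.path(out_dir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "network", config,
                 counts = summary[c("n_genes", "n_drugs", "n_gene_edges",
                                    "n_drug_edges")])
  invisible(net)
}

stage_drugsim <- function(config, out_dir) {
  th <- config$thresholds
  recs <- read_results(file.path(out_dir, "drug_records.tsv"))
  atc <- read_atc(file.path(config$bundle_dir, "atc.tsv"))
  tbl <- purrr::map_dfr(c("CSL", "CSV"), function(it) {
    sub <- dplyr::filter(recs, .data$itype == it)
    if (nrow(sub) == 0) return(tibble::tibble())
    dplyr::mutate(drug_pair_table(sub, atc, alpha = th$alpha),
                  itype = it, .before = 1)
  })
  readr::write_tsv(tbl, file.path(out_dir, "drug_pairs.tsv"), na = "",
                   progress = FALSE)
  write_manifest(out_dir, "drugsim", config, counts = list(
    n_pairs = nrow(tbl), n_similar = sum(tbl$similar %||% logical(0))
  ))
  invisible(tbl)
}

stage_validate <- function(config, out_dir) {
  th <- config$thresholds
  cons <- consensus_records(read_results(file.path(out_dir, "consensus.tsv")))
  co <- read_bundle_cohort(config$bundle_dir)
  report <- cohort_validation_report(co, cons, min_mut_freq = th$min_mut_freq,
                                     fdr = th$fdr, alpha = th$alpha)
  shifts <- purrr::map2_dfr(seq_len(nrow(report)), report$score_shifts,
                            function(i, s) {
    if (is.null(s)) return(tibble::tibble())
    dplyr::mutate(s, target = report$target[[i]], partner = report$partner[[i]],
                  .before = 1)
  })
  flat <- dplyr::select(report, -dplyr::any_of("score_shifts"))
  readr::write_tsv(flat, file.path(out_dir, "validation_report.tsv"), na = "",
                   progress = FALSE)
  readr::write_tsv(shifts, file.path(out_dir, "validation_score_shifts.tsv"),
                   na = "", progress = FALSE)
  pathways <- read_gmt(file.path(config$bundle_dir, "pathways.gmt"))
  universe <- rownames(co$expression)
  partner_genes <- unique(cons$partner)
  enr <- pathway_enrichment(partner_genes, pathways, universe, fdr = th$fdr)
  readr::write_tsv(enr, file.path(out_dir, "pathway_enrichment.tsv"),
                   progress = FALSE)
  write_manifest(out_dir, "validate", config, counts = list(
    n_interactions = nrow(report),
    n_analysed = sum(is.na(report$split_reason)),
    n_deregulating_expression = sum(report$n_expr_up + report$n_expr_down > 0,
                                    na.rm = TRUE),
    n_significant_pathways = sum(enr$significant)
  ))
  invisible(report)
}

stage_survival <- function(config, out_dir) {
  th <- config$thresholds
  cons <- consensus_records(read_results(file.path(out_dir, "consensus.tsv")))
  co <- read_bundle_cohort(config$bundle_dir)
  rule <- activation_rule("below")
  single <- purrr::map_dfr(seq_len(nrow(cons)), function(i) {
    fit <- single_pair_survival(co, cons$target[[i]], cons$partner[[i]],
                                min_mut_freq = th$min_mut_freq)
    tibble::tibble(target = cons$target[[i]], partner = cons$partner[[i]],
                   itype = cons$itype[[i]],
                   degenerate = fit$degenerate,
                   statistic = if (fit$degenerate) NA_real_ else fit$test$statistic,
                   p_value = if (fit$degenerate) NA_real_ else fit$test$p_value)
  })
  readr::write_tsv(single, file.path(out_dir, "survival_single_pair.tsv"),
                   na = "", progress = FALSE)
  csl <- dplyr::filter(cons, .data$itype == "CSL")
  burden_fit <- NULL
  if (nrow(csl) > 0) {
    counts <- count_activated(co, csl, rule)
    groups <- burden_groups(counts)
    readr::write_tsv(groups, file.path(out_dir, "survival_burden_groups.tsv"),
                     progress = FALSE)
    if (!attr(groups, "degenerate")) {
      burden_fit <- compare_survival(
        co, dplyr::transmute(groups, sample = .data$sample,
                             group = as.character(.data$group)))
    }
  }
  summary <- list(
    activation_rule = rule$side,
    n_single_tested = sum(!single$degenerate),
    n_single_significant = sum(single$p_value < th$alpha, na.rm = TRUE),
    burden_logrank_p = if (!is.null(burden_fit) && !burden_fit$degenerate)
      burden_fit$test$p_value
  )
  jsonlite::write_json(summary, file.path(out_dir, "survival_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(out_dir, "survival", config,
                 counts = summary[c("n_single_tested", "n_single_significant")])
  invisible(single)
}

PIPELINE_STAGES <- c("simulate", "screen-gi", "drug-filter", "network",
                     "drugsim", "validate", "survival")

#' Run one pipeline stage (or all of them)
#'
#' Each stage consumes and produces only files, so stages can be rerun
#' individually; rerunning with an identical config and seed reproduces the
#' outputs byte for byte. Every stage writes a `<stage>_manifest.json`
#' recording the seed, thresholds, a config hash, and the counts at each
#' filtering step.
#'
#' @param stage One of `"simulate"`, `"screen-gi"`, `"drug-filter"`,
#'   `"network"`, `"drugsim"`, `"validate"`, `"survival"`, `"run-all"`.
#' @param config Path to a YAML config or a named list (see
#'   [load_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the stage's primary result.
#' @export
run_stage <- function(stage, config = list(), out_dir = "crgi_run") {
  stage <- match.arg(stage, c(PIPELINE_STAGES, "run-all"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- load_config(config, out_dir)
  if (stage == "run-all") {
    for (s in PIPELINE_STAGES) run_stage(s, config, out_dir)
    return(invisible(out_dir))
  }
  fn <- switch(stage,
    "simulate" = stage_simulate, "screen-gi" = stage_screen_gi,
    "drug-filter" = stage_drug_filter, "network" = stage_network,
    "drugsim" = stage_drugsim, "validate" = stage_validate,
    "survival" = stage_survival)
  message("[crgi] stage ", stage, " (seed ", config$seed, ")")
  fn(config, out_dir)
}

#' Run the whole pipeline
#' @inheritParams run_stage
#' @export
run_pipeline <- function(config = list(), out_dir = "crgi_run") {
  run_stage("run-all", config, out_dir)
}
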