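#' Simulation configuration
#'
#' Defines the synthetic study: a shared cell-line panel screened by three
#' perturbation screens (one CERES-like, stored low-is-viable; two stored
#' high-is-viable), planted synthetic-lethal and synthetic-viable pairs at
#' a viability shift of `delta` noise SDs in partner-mutant lines,
#' pharmacogenomic response matrices with matching planted sensitivity or
#' resistance shifts, and a patient cohort with correlated expression /
#' methylation for planted pairs, mutation-plus-expression linked hazards
#' and independent censoring.
#'
#' Gene universe: `n_cr` chromatin regulators `CR001...` and
#' `n_genes - n_cr` other genes `G001...`. Planted pairs take their targets
#' from the non-CR genes and their partners from the CRs, so every pair has
#' a CR side. Additional CRs are mutated without any planted effect (null
#' partners), and `n_decoy_targets` unplanted targets define the null pair
#' universe for calibration.
#'
#' @param seed Integer seed; every generator derives its randomness from it.
#' @param n_genes,n_cr Gene universe sizes (default 200 genes, 100 CRs).
#' @param n_cell_lines Cell lines in the single-tissue panel (default 100).
#' @param tissue Tissue label (default "lung").
#' @param screens Tibble `name`, `orientation` for the screens.
#' @param sigma Noise SD of dependency scores (default 1).
#' @param delta Planted viability shift in units of `sigma` (default 2).
#' @param n_planted_csl,n_planted_csv Planted pair counts (default 20 / 10).
#' @param mutation_rate Per-line alteration probability for each mutated
#'   gene (default 0.3, i.e. 30 mutant / 70 wild-type lines in expectation).
#' @param mutation_model `"binomial"` (Bernoulli per line) or `"fixed"`
#'   (exactly `fixed_mutants` mutant lines per gene).
#' @param fixed_mutants Mutant-line count under `mutation_model = "fixed"`.
#' @param n_null_partners Mutated CRs with no planted effect (default 70).
#' @param n_decoy_targets Unplanted scan targets (default 2, giving a
#'   200-pair null universe in [sim_pairs()]: with a nominal-p two-of-three
#'   consensus the a-priori false-consensus rate is about 1.2% over both
#'   directions, so this universe keeps the expected false-discovery
#'   proportion of the planted recovery below 0.1).
#' @param mutation_flip_rate Per-screen probability of flipping a mutation
#'   call, emulating annotation discordance between catalogs (default 0).
#' @param drug_shift Planted drug-response shift in noise SDs (default 2).
#' @param n_null_drugs_per_target Decoy drugs per planted target with no
#'   response shift (default 1).
#' @param n_pharmaco_datasets Number of response datasets (default 2).
#' @param n_cohort_samples Cohort size (default 200).
#' @param rho Planted expression/methylation correlation (default 0.8).
#' @param cohort_mut_freq Partner mutation frequency in the cohort
#'   (default 0.15).
#' @param hazard_ratio Hazard multiplier for patients with >= 1 activated
#'   planted pair (default 2.5; synthetic-lethal activation is protective,
#'   so the multiplier applies to the *non*-activated CSL patients — see
#'   [generate_cohort()]).
#' @param censoring_rate Target censoring fraction (default 0.2).
#' @param base_hazard Baseline exponential hazard per day (default 1/365).
#' @param score_shift Planted per-sample score shift (default 1).
#' @param ppi_planted_fraction Fraction of planted pairs guaranteed a direct
#'   PPI edge (default 0.8).
#' @param ppi_extra_edges Random PPI edges (default 400).
#' @param n_pathways,pathway_size Random pathway collection shape.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200, n_cr = 100, n_cell_lines = 100,
                       tissue = "lung",
                       screens = tibble::tibble(
                         name = c("crispr_avana", "crispr_score", "shrna_achilles"),
                         orientation = c("low_is_viable", "high_is_viable",
                                         "high_is_viable")),
                       sigma = 1, delta = 2,
                       n_planted_csl = 20, n_planted_csv = 10,
                       mutation_rate = 0.3,
                       mutation_model = c("binomial", "fixed"),
                       fixed_mutants = NULL,
                       n_null_partners = 70, n_decoy_targets = 2,
                       mutation_flip_rate = 0,
                       drug_shift = 2, n_null_drugs_per_target = 1,
                       n_pharmaco_datasets = 2,
                       n_cohort_samples = 200, rho = 0.8,
                       cohort_mut_freq = 0.15, hazard_ratio = 2.5,
                       censoring_rate = 0.2, base_hazard = 1 / 365,
                       score_shift = 1,
                       ppi_planted_fraction = 0.8, ppi_extra_edges = 400,
                       n_pathways = 10, pathway_size = 15) {
  mutation_model <- match.arg(mutation_model)
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            mutation_flip_rate >= 0, mutation_flip_rate <= 1,
            censoring_rate >= 0, censoring_rate < 1,
            is.finite(delta), is.finite(rho), is.finite(hazard_ratio),
            abs(rho) <= 1)
  n_other <- n_genes - n_cr
  n_planted <- n_planted_csl + n_planted_csv
  if (n_other < n_planted + n_decoy_targets) {
    abort("sim_config: not enough non-CR genes for planted + decoy targets")
  }
  if (n_cr < n_planted + n_null_partners) {
    abort("sim_config: not enough CR genes for planted + null partners")
  }
  cr_genes <- sprintf("CR%03d", seq_len(n_cr))
  other_genes <- sprintf("G%03d", seq_len(n_other))
  planted <- tibble::tibble(
    target = other_genes[seq_len(n_planted)],
    partner = cr_genes[seq_len(n_planted)],
    itype = rep(c("CSL", "CSV"), c(n_planted_csl, n_planted_csv))
  )
  decoy_targets <- other_genes[n_planted + seq_len(n_decoy_targets)]
  null_partners <- cr_genes[n_planted + seq_len(n_null_partners)]
  structure(list(
    seed = as.integer(seed), n_genes = n_genes, n_cr = n_cr,
    genes = c(cr_genes, other_genes), cr_genes = cr_genes,
    n_cell_lines = n_cell_lines, tissue = tissue, screens = screens,
    sigma = sigma, delta = delta, planted = planted,
    decoy_targets = decoy_targets, null_partners = null_partners,
    mutation_rate = mutation_rate, mutation_model = mutation_model,
    fixed_mutants = fixed_mutants, mutation_flip_rate = mutation_flip_rate,
    drug_shift = drug_shift, n_null_drugs_per_target = n_null_drugs_per_target,
    n_pharmaco_datasets = n_pharmaco_datasets,
    n_cohort_samples = n_cohort_samples, rho = rho,
    cohort_mut_freq = cohort_mut_freq, hazard_ratio = hazard_ratio,
    censoring_rate = censoring_rate, base_hazard = base_hazard,
    score_shift = score_shift,
    ppi_planted_fraction = ppi_planted_fraction,
    ppi_extra_edges = ppi_extra_edges,
    n_pathways = n_pathways, pathway_size = pathway_size
  ), class = "sim_config")
}

#' Pairs to scan in a simulated bundle
#'
#' The planted pairs plus the null universe (decoy targets crossed with all
#' mutated partners).
#'
#' @param config A [sim_config()].
#' @return Tibble `target`, `partner` with a logical `planted` column and
#'   the planted `itype` (`NA` for null pairs).
#' @export
sim_pairs <- function(config) {
  partners <- c(config$planted$partner, config$null_partners)
  null_pairs <- tidyr::expand_grid(target = config$decoy_targets,
                                   partner = partners)
  dplyr::bind_rows(
    dplyr::mutate(config$planted, planted = TRUE),
    dplyr::mutate(null_pairs, itype = NA_character_, planted = FALSE)
  )
}

mutation_class_probs <- c(missense = 0.55, nonsense = 0.2, frameshift = 0.1,
                          splice = 0.05, other = 0.05, silent = 0.05)

draw_mutations <- function(config, samples, genes, rate) {
  fixed <- config$mutation_model == "fixed" && !is.null(config$fixed_mutants)
  # the fixed model exists to plant exact mutant group sizes, so it draws
  # altering classes only; the binomial model includes silent calls
  probs <- if (fixed) {
    mutation_class_probs[setdiff(names(mutation_class_probs), "silent")]
  } else {
    mutation_class_probs
  }
  recs <- purrr::map_dfr(genes, function(g) {
    hit <- if (fixed) {
      sample(samples, config$fixed_mutants)
    } else {
      samples[runif(length(samples)) < rate]
    }
    if (length(hit) == 0) return(tibble::tibble())
    tibble::tibble(sample = hit, gene = g,
                   mutation_class = sample(names(probs), length(hit),
                                           replace = TRUE, prob = probs))
  })
  if (nrow(recs) == 0) {
    recs <- tibble::tibble(sample = character(0), gene = character(0),
                           mutation_class = character(0))
  }
  mutation_catalog(recs)
}

flip_calls <- function(config, truth, samples, genes) {
  if (config$mutation_flip_rate == 0) return(truth)
  grid <- tidyr::expand_grid(sample = samples, gene = genes)
  called <- dplyr::mutate(
    dplyr::left_join(grid,
                     dplyr::mutate(dplyr::distinct(truth[truth$altering,
                                                         c("sample", "gene")]),
                                   mut = TRUE),
                     by = c("sample", "gene")),
    mut = !is.na(.data$mut),
    flip = runif(dplyr::n()) < config$mutation_flip_rate,
    called = xor(.data$mut, .data$flip)
  )
  keep <- dplyr::filter(called, .data$called)
  mutation_catalog(tibble::tibble(
    sample = keep$sample, gene = keep$gene,
    mutation_class = sample(setdiff(names(mutation_class_probs), "silent"),
                            nrow(keep), replace = TRUE)
  ))
}

#' Generate perturbation screens with planted interactions
#'
#' Baseline viability scores are i.i.d. normal(0, sigma). For each planted
#' synthetic-lethal pair the target's scores in partner-altered lines are
#' shifted by `-delta * sigma` (on the viability orientation); planted
#' synthetic-viable pairs are shifted by `+delta * sigma`. Each screen gets
#' independent noise but the same planted semantics; screens declared
#' `low_is_viable` are stored negated, as their real-world counterparts
#' publish essentiality. Mutation calls are shared across screens unless
#' `mutation_flip_rate > 0`.
#'
#' @param config A [sim_config()].
#' @return List: `screens` (list of [screen_dataset()]), `mutations` (named
#'   list of per-screen [mutation_catalog()]s), `truth` (the base catalog),
#'   `lineages`.
#' @export
generate_screens <- function(config) {
  withr_seed(config$seed + 1L, {
    lines <- sprintf("CL%03d", seq_len(config$n_cell_lines))
    lineages <- tibble::tibble(cell_line = lines, tissue = config$tissue)
    mutated_genes <- c(config$planted$partner, config$null_partners)
    bad <- setdiff(c(config$planted$target, config$planted$partner), config$genes)
    if (length(bad) > 0) abort(paste0("planted pair references unknown gene: ", bad[[1]]))
    truth <- draw_mutations(config, lines, mutated_genes, config$mutation_rate)
    screens <- vector("list", nrow(config$screens))
    catalogs <- vector("list", nrow(config$screens))
    for (s in seq_len(nrow(config$screens))) {
      scores <- matrix(rnorm(length(config$genes) * length(lines),
                             sd = config$sigma),
                       nrow = length(config$genes),
                       dimnames = list(config$genes, lines))
      for (i in seq_len(nrow(config$planted))) {
        pr <- config$planted[i, ]
        mut_lines <- altered_samples(truth, pr$partner)
        shift <- if (pr$itype == "CSL") -config$delta * config$sigma
                 else config$delta * config$sigma
        scores[pr$target, mut_lines] <- scores[pr$target, mut_lines] + shift
      }
      orient <- config$screens$orientation[[s]]
      if (orient == "low_is_viable") scores <- -scores
      screens[[s]] <- screen_dataset(scores, lineages,
                                     config$screens$name[[s]], orient)
      catalogs[[s]] <- flip_calls(config, truth, lines, mutated_genes)
    }
    names(catalogs) <- config$screens$name
    list(screens = screens, mutations = catalogs, truth = truth,
         lineages = lineages)
  })
}

#' Drug-target map implied by a simulation config
#'
#' One planted drug per planted target plus `n_null_drugs_per_target`
#' decoy drugs (measured, but with no planted response shift).
#'
#' @param config A [sim_config()].
#' @return A [drug_target_map()] with a logical attribute-free `planted`
#'   encoded in the drug name (`drug_*` vs `nulldrug_*`).
#' @export
sim_drug_targets <- function(config) {
  planted <- tibble::tibble(drug = paste0("drug_", config$planted$target),
                            target = config$planted$target)
  nulls <- purrr::map_dfr(seq_len(config$n_null_drugs_per_target), function(j) {
    tibble::tibble(drug = paste0("nulldrug", j, "_", config$planted$target),
                   target = config$planted$target)
  })
  drug_target_map(dplyr::bind_rows(planted, nulls))
}

#' Generate pharmacogenomic response datasets
#'
#' Responses are normal around a per-drug baseline; partner-altered lines
#' of planted synthetic-lethal pairs respond lower (sensitive) by
#' `drug_shift` SDs for the drug hitting the pair's target, planted
#' synthetic-viable pairs higher (resistant). Decoy drugs carry no shift.
#' Noise is independent per dataset.
#'
#' @param config A [sim_config()].
#' @param truth Base [mutation_catalog()] from [generate_screens()].
#' @param lineages Cell-line/tissue tibble from [generate_screens()].
#' @return List of [drug_response_dataset()]s.
#' @export
generate_pharmaco <- function(config, truth, lineages) {
  withr_seed(config$seed + 2L, {
    map <- sim_drug_targets(config)
    drugs <- unique(map$drug)
    lines <- lineages$cell_line
    metrics <- rep(c("AUC", "IC50"), length.out = config$n_pharmaco_datasets)
    purrr::map(seq_len(config$n_pharmaco_datasets), function(d) {
      resp <- matrix(rnorm(length(drugs) * length(lines)),
                     nrow = length(drugs), dimnames = list(drugs, lines))
      for (i in seq_len(nrow(config$planted))) {
        pr <- config$planted[i, ]
        drug <- paste0("drug_", pr$target)
        mut_lines <- altered_samples(truth, pr$partner)
        shift <- if (pr$itype == "CSL") -config$drug_shift else config$drug_shift
        resp[drug, mut_lines] <- resp[drug, mut_lines] + shift
      }
      drug_response_dataset(resp, lineages, paste0("pharmaco", d),
                            metric = metrics[[d]])
    })
  })
}

#' Generate a TCGA-like patient cohort
#'
#' Expression and methylation are standard normal per gene with planted
#' pairwise correlation `rho` between each planted target and partner.
#' Partner genes are mutated at `cohort_mut_freq`. Survival times are
#' exponential: patients with at least one activated planted pair (partner
#' altered and target expression at or below the cohort median) have their
#' hazard divided by `hazard_ratio` for synthetic-lethal pairs (activation
#' is protective) and multiplied by it for synthetic-viable pairs, and
#' censoring is independent exponential tuned to `censoring_rate`.
#' Per-sample scores (HRD components and immune fractions) are shifted by
#' `score_shift` in samples where the first planted synthetic-lethal pair
#' is activated.
#'
#' @param config A [sim_config()].
#' @return A [cohort()].
#' @export
generate_cohort <- function(config) {
  withr_seed(config$seed + 3L, {
    samples <- sprintf("PT%03d", seq_len(config$n_cohort_samples))
    genes <- config$genes
    correlated_matrix <- function() {
      m <- matrix(rnorm(length(genes) * length(samples)),
                  nrow = length(genes), dimnames = list(genes, samples))
      for (i in seq_len(nrow(config$planted))) {
        pr <- config$planted[i, ]
        m[pr$partner, ] <- config$rho * m[pr$target, ] +
          sqrt(1 - config$rho^2) * rnorm(length(samples))
      }
      m
    }
    expression <- correlated_matrix()
    methylation <- correlated_matrix()
    mutations <- draw_mutations(config, samples,
                                c(config$planted$partner, config$null_partners),
                                config$cohort_mut_freq)
    hazard <- rep(config$base_hazard, length(samples))
    names(hazard) <- samples
    med <- apply(expression, 1, median)
    for (i in seq_len(nrow(config$planted))) {
      pr <- config$planted[i, ]
      act <- intersect(altered_samples(mutations, pr$partner),
                       samples[expression[pr$target, ] <= med[[pr$target]]])
      if (pr$itype == "CSL") {
        hazard[act] <- hazard[act] / config$hazard_ratio
      } else {
        hazard[act] <- hazard[act] * config$hazard_ratio
      }
    }
    event_time <- rexp(length(samples), rate = hazard)
    cens_rate <- config$base_hazard * config$censoring_rate /
      max(1 - config$censoring_rate, 1e-6)
    censor_time <- if (cens_rate > 0) rexp(length(samples), rate = cens_rate)
                   else rep(Inf, length(samples))
    surv <- tibble::tibble(
      sample = samples,
      time = pmin(event_time, censor_time),
      event = as.integer(event_time <= censor_time)
    )
    score_names <- c("HRD", "TAI", "LST", "LOH",
                     "B_cells_memory", "Macrophages_M2")
    scores <- matrix(rnorm(length(score_names) * length(samples)),
                     nrow = length(score_names),
                     dimnames = list(score_names, samples))
    first_csl <- config$planted[config$planted$itype == "CSL", ][1, ]
    if (!is.na(first_csl$target)) {
      act <- intersect(altered_samples(mutations, first_csl$partner),
                       samples[expression[first_csl$target, ] <=
                                 med[[first_csl$target]]])
      scores[c("HRD", "TAI", "LST", "LOH"), act] <-
        scores[c("HRD", "TAI", "LST", "LOH"), act] + config$score_shift
      scores["Macrophages_M2", act] <- scores["Macrophages_M2", act] -
        config$score_shift
    }
    cohort(expression, surv, mutations, methylation = methylation,
           sample_scores = scores, cancer_type = "synthetic")
  })
}

#' Generate side data: PPI, pathways, ATC codes, cancer genes
#'
#' The PPI graph is a sparse random graph over the gene universe plus a
#' guaranteed direct edge for `ppi_planted_fraction` of the planted pairs.
#' The pathway collection is random sets plus one set holding the planted
#' partners. Drugs sharing a target share an ATC code. Cancer genes are a
#' random slice of the universe enriched for planted partners.
#'
#' @param config A [sim_config()].
#' @return List: `ppi` ([ppi_graph()]), `pathways` (named list), `atc`
#'   (named list), `cancer_genes` (character).
#' @export
generate_side_data <- function(config) {
  withr_seed(config$seed + 4L, {
    genes <- config$genes
    extra <- tibble::tibble(
      gene_a = sample(genes, config$ppi_extra_edges, replace = TRUE),
      gene_b = sample(genes, config$ppi_extra_edges, replace = TRUE)
    )
    extra <- dplyr::filter(extra, .data$gene_a != .data$gene_b)
    n_direct <- round(config$ppi_planted_fraction * nrow(config$planted))
    direct <- if (n_direct > 0) {
      idx <- sample(nrow(config$planted), n_direct)
      tibble::tibble(gene_a = config$planted$target[idx],
                     gene_b = config$planted$partner[idx])
    } else tibble::tibble(gene_a = character(0), gene_b = character(0))
    ppi <- ppi_graph(dplyr::bind_rows(extra, direct))
    pathways <- setNames(
      lapply(seq_len(config$n_pathways), function(i) {
        sample(genes, config$pathway_size)
      }),
      sprintf("pathway_%02d", seq_len(config$n_pathways))
    )
    pathways[["planted_partner_program"]] <- unique(config$planted$partner)
    map <- sim_drug_targets(config)
    atc <- lapply(split(map$target, map$drug), function(tg) {
      sprintf("L01%s", toupper(substr(gsub("[^A-Za-z0-9]", "", tg), 1, 4)))
    })
    cancer_genes <- unique(c(
      sample(genes, round(0.2 * length(genes))),
      sample(config$planted$partner,
             round(0.5 * nrow(config$planted)))
    ))
    list(ppi = ppi, pathways = pathways, atc = atc, cancer_genes = cancer_genes)
  })
}

#' Write a complete simulated input bundle to disk
#'
#' Emits every file the pipeline consumes, in the package's TSV/GMT
#' formats, plus a manifest JSON recording the configuration.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the list of generated in-memory objects.
#' @export
simulate_bundle <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "screens"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "pharmaco"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "cohort"), showWarnings = FALSE)
  scr <- generate_screens(config)
  for (s in scr$screens) {
    write_matrix(s$scores, file.path(out_dir, "screens",
                                     paste0(s$name, "_scores.tsv")), "gene")
    write_mutations(scr$mutations[[s$name]],
                    file.path(out_dir, "screens", paste0(s$name, "_mutations.tsv")))
  }
  readr::write_tsv(scr$lineages, file.path(out_dir, "lineages.tsv"),
                   progress = FALSE)
  screen_meta <- dplyr::mutate(config$screens,
                               scores = paste0("screens/", .data$name, "_scores.tsv"),
                               mutations = paste0("screens/", .data$name, "_mutations.tsv"))
  readr::write_tsv(screen_meta, file.path(out_dir, "screens.tsv"), progress = FALSE)
  ph <- generate_pharmaco(config, scr$truth, scr$lineages)
  for (d in ph) {
    write_matrix(d$responses, file.path(out_dir, "pharmaco",
                                        paste0(d$name, "_responses.tsv")), "drug")
  }
  readr::write_tsv(
    tibble::tibble(name = vapply(ph, `[[`, character(1), "name"),
                   metric = vapply(ph, `[[`, character(1), "metric"),
                   responses = paste0("pharmaco/",
                                      vapply(ph, `[[`, character(1), "name"),
                                      "_responses.tsv")),
    file.path(out_dir, "pharmaco.tsv"), progress = FALSE)
  write_mutations(scr$truth, file.path(out_dir, "pharmaco", "mutations.tsv"))
  readr::write_tsv(sim_drug_targets(config),
                   file.path(out_dir, "drug_targets.tsv"), progress = FALSE)
  side <- generate_side_data(config)
  readr::write_tsv(side$ppi, file.path(out_dir, "ppi.tsv"), progress = FALSE)
  write_gmt(side$pathways, file.path(out_dir, "pathways.gmt"))
  readr::write_tsv(
    tibble::tibble(drug = rep(names(side$atc),
                              vapply(side$atc, length, integer(1))),
                   atc_code = unlist(side$atc, use.names = FALSE)),
    file.path(out_dir, "atc.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(gene = sort(side$cancer_genes)),
                   file.path(out_dir, "cancer_genes.tsv"), progress = FALSE)
  readr::write_tsv(tibble::tibble(gene = config$cr_genes),
                   file.path(out_dir, "cr_genes.tsv"), progress = FALSE)
  co <- generate_cohort(config)
  write_matrix(co$expression, file.path(out_dir, "cohort", "expression.tsv"), "gene")
  write_matrix(co$methylation, file.path(out_dir, "cohort", "methylation.tsv"), "gene")
  write_mutations(co$mutations, file.path(out_dir, "cohort", "mutations.tsv"))
  readr::write_tsv(co$survival, file.path(out_dir, "cohort", "survival.tsv"),
                   progress = FALSE)
  write_matrix(co$sample_scores, file.path(out_dir, "cohort", "sample_scores.tsv"),
               "score")
  readr::write_tsv(dplyr::mutate(config$planted, planted = TRUE),
                   file.path(out_dir, "truth_pairs.tsv"), progress = FALSE)
  manifest <- list(
    generator = "crgi::simulate_bundle", seed = config$seed,
    n_genes = config$n_genes, n_cr = config$n_cr,
    n_cell_lines = config$n_cell_lines, tissue = config$tissue,
    sigma = config$sigma, delta = config$delta,
    n_planted_csl = sum(config$planted$itype == "CSL"),
    n_planted_csv = sum(config$planted$itype == "CSV"),
    mutation_rate = config$mutation_rate,
    drug_shift = config$drug_shift,
    n_pharmaco_datasets = config$n_pharmaco_datasets,
    n_cohort_samples = config$n_cohort_samples,
    rho = config$rho, hazard_ratio = config$hazard_ratio,
    censoring_rate = config$censoring_rate
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(screens = scr, pharmaco = ph, side = side, cohort = co,
                 config = config))
}
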