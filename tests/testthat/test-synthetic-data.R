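small_cfg <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 60, n_cr = 25, n_cell_lines = 50,
         n_planted_csl = 4, n_planted_csv = 2, n_null_partners = 10,
         n_decoy_targets = 2, n_cohort_samples = 80, ppi_extra_edges = 100),
    list(...))
  do.call(sim_config, args)
}

test_that("generators are deterministic under a fixed seed", {
  a <- generate_screens(small_cfg())
  b <- generate_screens(small_cfg())
  expect_identical(a$screens[[1]]$scores, b$screens[[1]]$scores)
  expect_identical(a$mutations, b$mutations)
  c1 <- generate_cohort(small_cfg())
  c2 <- generate_cohort(small_cfg())
  expect_identical(c1$expression, c2$expression)
  expect_identical(c1$survival, c2$survival)
  s1 <- generate_side_data(small_cfg())
  s2 <- generate_side_data(small_cfg())
  expect_identical(s1$ppi, s2$ppi)
  # a different seed moves the data
  expect_false(identical(generate_screens(small_cfg(seed = 6))$screens[[1]]$scores,
                         a$screens[[1]]$scores))
})

test_that("screen generator respects orientation and planted shifts", {
  cfg <- small_cfg()
  scr <- generate_screens(cfg)
  orientations <- vapply(scr$screens, `[[`, character(1), "orientation")
  expect_equal(orientations, cfg$screens$orientation)
  # the CERES-like screen stores negated viability: orienting it must
  # reproduce the same planted direction as the native screens
  pair <- cfg$planted[1, ]
  mut_lines <- altered_samples(scr$truth, pair$partner)
  for (s in scr$screens) {
    v <- orient_to_viability(s)$scores[pair$target, ]
    gap <- mean(v[mut_lines]) - mean(v[setdiff(names(v), mut_lines)])
    expect_lt(gap, 0)  # synthetic-lethal pair: mutants less viable
  }
})

test_that("planted pairs referencing unknown genes are rejected", {
  cfg <- small_cfg()
  cfg$planted$target[1] <- "NOT_A_GENE"
  expect_error(generate_screens(cfg), "unknown gene")
})

test_that("fixed mutation model plants exact group sizes", {
  cfg <- small_cfg(mutation_model = "fixed", fixed_mutants = 15)
  scr <- generate_screens(cfg)
  genes <- unique(scr$truth$gene)
  counts <- vapply(genes, function(g) {
    length(unique(scr$truth$sample[scr$truth$gene == g]))
  }, integer(1))
  expect_true(all(counts == 15))
})

test_that("a zero effect size leaves planted pairs at the null candidate rate", {
  cfg <- small_cfg(delta = 0, n_null_partners = 14)
  scr <- generate_screens(cfg)
  cands <- scan_candidates(scr$screens, scr$mutations, cfg$cr_genes,
                           pairs = sim_pairs(cfg)[, c("target", "partner")],
                           keep_all = TRUE)
  rate <- mean(cands$p_lethal[cands$tested] < 0.05)
  n <- sum(cands$tested)
  ci <- qbinom(c(0.0005, 0.9995), n, 0.05) / n
  expect_gte(rate, ci[[1]])
  expect_lte(rate, ci[[2]])
})

test_that("cohort generator plants correlation, mutations and consistent tables", {
  cfg <- small_cfg()
  co <- generate_cohort(cfg)
  expect_true(all(co$survival$time >= 0))
  expect_true(all(co$survival$event %in% c(0, 1)))
  expect_setequal(colnames(co$methylation), cohort_samples(co))
  pair <- cfg$planted[1, ]
  expect_gt(cor(co$expression[pair$target, ], co$expression[pair$partner, ]),
            0.55)
  freq <- length(altered_samples(co$mutations, pair$partner)) /
    cfg$n_cohort_samples
  expect_gt(freq, 0.03)
  expect_lt(freq, 0.4)
})

test_that("side data guarantees the configured fraction of planted PPI edges", {
  cfg <- small_cfg(ppi_planted_fraction = 1, ppi_extra_edges = 30)
  side <- generate_side_data(cfg)
  planted_edges <- tibble::tibble(
    gene_a = pmin(cfg$planted$target, cfg$planted$partner),
    gene_b = pmax(cfg$planted$target, cfg$planted$partner))
  found <- dplyr::inner_join(planted_edges, side$ppi,
                             by = c("gene_a", "gene_b"))
  expect_equal(nrow(found), nrow(cfg$planted))
  net <- build_network(cfg$planted)
  res <- ppi_overlap_test(net, side$ppi, n_perm = 49, seed = 1)
  expect_equal(res$observed_rate, 1)

  half <- generate_side_data(small_cfg(ppi_planted_fraction = 0.5))
  half_found <- dplyr::inner_join(planted_edges, half$ppi,
                                  by = c("gene_a", "gene_b"))
  expect_gte(nrow(half_found), round(0.5 * nrow(cfg$planted)))
  expect_true("planted_partner_program" %in% names(half$pathways))
})

test_that("bundle files round-trip through the package readers", {
  cfg <- small_cfg()
  out <- withr::local_tempdir()
  objs <- simulate_bundle(cfg, out)
  expect_true(file.exists(file.path(out, "manifest.json")))
  scores <- read_matrix(
    file.path(out, "screens", "crispr_avana_scores.tsv"))
  expect_equal(scores, objs$screens$screens[[1]]$scores, tolerance = 1e-12)
  muts <- read_mutations(file.path(out, "cohort", "mutations.tsv"))
  expect_equal(sort(unique(muts$gene)),
               sort(unique(objs$cohort$mutations$gene)))
  gmt <- read_gmt(file.path(out, "pathways.gmt"))
  expect_equal(gmt, objs$side$pathways)
})
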