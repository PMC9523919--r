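make_test_cohort <- function(n = 40, seed = 1, mut_samples = NULL,
                             expr = NULL) {
  set.seed(seed)
  samples <- sprintf("P%03d", seq_len(n))
  genes <- c("TGT", "PRT", sprintf("G%02d", 1:8))
  if (is.null(expr)) {
    expr <- matrix(rnorm(length(genes) * n), length(genes),
                   dimnames = list(genes, samples))
  }
  if (is.null(mut_samples)) mut_samples <- samples[1:20]
  cohort(
    expression = expr,
    survival = tibble::tibble(sample = samples,
                              time = rexp(n, 1 / 100),
                              event = rbinom(n, 1, 0.8)),
    mutations = make_mutations(mut_samples, "PRT"),
    methylation = expr + rnorm(length(expr), sd = 0.1),
    sample_scores = matrix(rnorm(2 * n), 2,
                           dimnames = list(c("HRD", "TIL"), samples))
  )
}

test_that("pairwise correlation classifies planted, null and self pairs", {
  set.seed(12)
  n <- 200
  tgt <- rnorm(n)
  prt <- 0.8 * tgt + sqrt(1 - 0.64) * rnorm(n)
  indep <- rnorm(n)
  mat <- rbind(TGT = tgt, PRT = prt, IND = indep)
  colnames(mat) <- sprintf("P%03d", 1:n)
  res <- pairwise_correlation(mat, tibble::tibble(
    target = c("TGT", "TGT", "TGT", "TGT"),
    partner = c("PRT", "IND", "TGT", "MISSING")))
  expect_equal(res$class[1], "positive")
  expect_gt(res$r[1], 0.6)
  expect_equal(res$class[3], "positive")
  expect_equal(res$r[3], 1)
  expect_equal(res$reason[4], "gene_not_measured")

  # null-pair calibration: positive+negative rate stays near alpha
  set.seed(33)
  null_mat <- matrix(rnorm(100 * 60), 100,
                     dimnames = list(sprintf("N%03d", 1:100),
                                     sprintf("P%03d", 1:60)))
  pairs <- tibble::tibble(target = sprintf("N%03d", 1:50),
                          partner = sprintf("N%03d", 51:100))
  calls <- pairwise_correlation(null_mat, pairs)
  expect_lte(mean(calls$class != "none"), 0.2)
})

test_that("median split keeps ties in the low group and enforces the frequency rule", {
  co <- make_test_cohort()
  sp <- split_by_target_median(co, "TGT", "PRT")
  expect_true(split_ok(sp))
  expect_equal(length(sp$low), 10)
  expect_equal(length(sp$high), 10)
  expect_true(all(co$expression["TGT", sp$low] <= sp$median))

  rare <- make_test_cohort(n = 50, mut_samples = sprintf("P%03d", 1:4))
  skip <- split_by_target_median(rare, "TGT", "PRT")
  expect_false(split_ok(skip))
  expect_equal(skip$reason, "mutation_frequency_below_threshold")

  flat <- make_test_cohort(expr = matrix(
    1, 10, 40, dimnames = list(c("TGT", "PRT", sprintf("G%02d", 1:8)),
                               sprintf("P%03d", 1:40))))
  tied <- split_by_target_median(flat, "TGT", "PRT")
  expect_equal(length(tied$high), 0)
  expect_true(tied$degenerate)
})

test_that("differential features are directional, disjoint and FDR-nested", {
  co <- make_test_cohort(n = 60, seed = 7,
                         mut_samples = sprintf("P%03d", 1:30))
  sp <- split_by_target_median(co, "TGT", "PRT")
  same <- differential_features(co$expression, sp)
  expect_true(length(intersect(same$up, same$down)) == 0)

  all_feats <- differential_features(co$expression, sp, fdr = 1)
  expect_setequal(c(all_feats$up, all_feats$down), rownames(co$expression))

  strict <- differential_features(co$expression, sp, fdr = 0.01)
  loose <- differential_features(co$expression, sp, fdr = 0.1)
  expect_true(all(strict$up %in% loose$up))
  expect_true(all(strict$down %in% loose$down))

  tiny <- manual_split(sp$low[1:2], sp$high)
  expect_error(differential_features(co$expression, tiny), "fewer than 3")
})

test_that("identical groups yield no differential features", {
  mat <- matrix(rep(1:10, 12), 10,
                dimnames = list(sprintf("F%02d", 1:10), sprintf("S%02d", 1:12)))
  sp <- manual_split(sprintf("S%02d", 1:6), sprintf("S%02d", 7:12))
  res <- differential_features(mat, sp)
  expect_equal(length(res$up), 0)
  expect_equal(length(res$down), 0)
})

test_that("score shifts report the smaller-p direction", {
  samples <- sprintf("S%02d", 1:20)
  sp <- manual_split(samples[1:10], samples[11:20])
  up <- setNames(c(rnorm(10, 3), rnorm(10, 0)), samples)
  res <- score_shift_test(up, sp)
  expect_equal(res$direction, "up")
  expect_true(res$significant)

  set.seed(8)
  null_score <- setNames(rnorm(20), samples)
  nres <- score_shift_test(null_score, sp)
  expect_false(nres$degenerate)

  flat <- setNames(rep(2, 20), samples)
  fres <- score_shift_test(flat, sp)
  expect_true(fres$degenerate)
  expect_equal(fres$p_value, 1)
})

test_that("pathway enrichment ranks a fully recovered pathway first", {
  set.seed(19)
  universe <- sprintf("U%03d", 1:100)
  pathways <- setNames(lapply(1:10, function(i) sample(universe, 8)),
                       sprintf("pw%02d", 1:10))
  pathways$hit <- universe[1:5]
  res <- pathway_enrichment(universe[1:5], pathways, universe)
  expect_equal(res$pathway[[1]], "hit")
  expect_equal(res$p[[1]], 1 / choose(100, 5) * choose(95, 0) * choose(5, 5))

  disjoint <- pathway_enrichment("U100", list(pw = universe[1:5]), universe)
  expect_false(any(disjoint$significant))

  saturated <- pathway_enrichment(universe, pathways, universe)
  expect_true(all(saturated$p == 1))
  expect_error(pathway_enrichment(universe[1:5], list(), universe), "empty")
})

test_that("cohort validation report summarises planted structure", {
  set.seed(44)
  n <- 80
  samples <- sprintf("P%03d", seq_len(n))
  tgt <- rnorm(n)
  genes <- c("TGT", "PRT", sprintf("G%02d", 1:18))
  expr <- matrix(rnorm(20 * n), 20, dimnames = list(genes, samples))
  expr["TGT", ] <- tgt
  expr["PRT", ] <- 0.85 * tgt + sqrt(1 - 0.85^2) * rnorm(n)
  co <- cohort(
    expression = expr,
    survival = tibble::tibble(sample = samples, time = rexp(n, 0.01),
                              event = rbinom(n, 1, 0.8)),
    mutations = make_mutations(samples[1:30], "PRT"),
    methylation = expr + rnorm(length(expr), sd = 0.3),
    sample_scores = matrix(rnorm(n), 1, dimnames = list("HRD", samples))
  )
  rep <- cohort_validation_report(
    co, tibble::tibble(target = "TGT", partner = "PRT", itype = "CSL"))
  expect_equal(rep$expr_class, "positive")
  expect_equal(rep$meth_class, "positive")
  expect_true(rep$n_low >= 3 && rep$n_high >= 3)
  # the target itself must read as differentially expressed between its
  # own low/high groups
  expect_true(rep$n_expr_down >= 1)
  expect_s3_class(rep$score_shifts[[1]], "tbl_df")
})
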