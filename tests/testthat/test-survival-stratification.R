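surv_cohort <- function(n = 60, seed = 3, mut = list(PRT = 1:20),
                        expr_genes = c("TGT", "PRT")) {
  set.seed(seed)
  samples <- sprintf("P%03d", seq_len(n))
  expr <- matrix(rnorm(length(expr_genes) * n), length(expr_genes),
                 dimnames = list(expr_genes, samples))
  recs <- purrr::imap_dfr(mut, function(idx, gene) {
    tibble::tibble(sample = samples[idx], gene = gene,
                   mutation_class = "missense")
  })
  cohort(expression = expr,
         survival = tibble::tibble(sample = samples, time = rexp(n, 0.01),
                                   event = rbinom(n, 1, 0.8)),
         mutations = mutation_catalog(recs))
}

test_that("activation requires partner mutation and target-low expression", {
  co <- surv_cohort()
  rule <- activation_rule("below")
  ints <- tibble::tibble(target = "TGT", partner = "PRT")
  counts <- count_activated(co, ints, rule)
  med <- median(co$expression["TGT", ])
  manual <- intersect(altered_samples(co$mutations, "PRT"),
                      colnames(co$expression)[co$expression["TGT", ] <= med])
  expect_setequal(counts$sample[counts$count == 1], manual)
  # unmutated patients always count zero
  expect_true(all(counts$count[!counts$sample %in%
                                 altered_samples(co$mutations, "PRT")] == 0))

  # two activated pairs count twice
  co2 <- surv_cohort(mut = list(PRT = 1:20, PRT2 = 1:20),
                     expr_genes = c("TGT", "TGT2", "PRT", "PRT2"))
  ints2 <- tibble::tibble(target = c("TGT", "TGT2"), partner = c("PRT", "PRT2"))
  c2 <- count_activated(co2, ints2, rule)
  low_both <- colnames(co2$expression)[
    co2$expression["TGT", ] <= median(co2$expression["TGT", ]) &
    co2$expression["TGT2", ] <= median(co2$expression["TGT2", ])]
  expect_setequal(c2$sample[c2$count == 2],
                  intersect(sprintf("P%03d", 1:20), low_both))

  above <- count_activated(co, ints, activation_rule("above"))
  expect_equal(sum(above$count) + sum(counts$count),
               length(altered_samples(co$mutations, "PRT")))
})

test_that("burden groups partition patients with ties going low", {
  counts <- tibble::tibble(sample = sprintf("P%d", 1:6),
                           count = c(0, 0, 1, 1, 2, 3))
  g <- burden_groups(counts)
  expect_equal(sum(g$group == "none"), 2)
  expect_setequal(g$count[g$group == "fewer"], c(1, 1))
  expect_setequal(g$count[g$group == "more"], c(2, 3))
  expect_equal(nrow(g), 6)

  allz <- burden_groups(tibble::tibble(sample = "a", count = 0))
  expect_true(attr(allz, "degenerate"))
  expect_equal(as.character(allz$group), "none")

  equal <- burden_groups(tibble::tibble(sample = sprintf("P%d", 1:4),
                                        count = rep(2, 4)))
  expect_true(all(equal$group == "fewer"))
})

test_that("modules pool partners of one target and reject mixed types", {
  ints <- tibble::tibble(
    target = "MAP2", partner = c("TRRAP", "EP300", "NSD2", "MSH6"),
    tissue = "colon", itype = "CSL", drug = c("paclitaxel", "docetaxel",
                                              "paclitaxel", "docetaxel"))
  mod <- build_module(ints, "MAP2", "colon")
  expect_equal(length(mod$partners), 4)
  expect_setequal(mod$drugs, c("paclitaxel", "docetaxel"))
  expect_equal(mod$itype, "CSL")

  single <- build_module(ints[1, ], "MAP2", "colon")
  expect_equal(single$partners, "TRRAP")

  mixed <- dplyr::mutate(ints, itype = c("CSL", "CSV", "CSL", "CSL"))
  expect_error(build_module(mixed, "MAP2", "colon"), "mixed")
  expect_error(build_module(ints, "NOPE", "colon"), "no interaction")
})

test_that("module carrier fraction dominates single-partner frequencies", {
  co <- surv_cohort(n = 80, mut = list(A = 1:10, B = 11:18, C = 40:44),
                    expr_genes = c("TGT", "A", "B", "C"))
  ints <- tibble::tibble(target = "TGT", partner = c("A", "B", "C"),
                         tissue = "lung", itype = "CSV")
  mod <- build_module(ints, "TGT", "lung")
  split <- module_carrier_split(co, mod, style = "carrier",
                                rule = activation_rule("below"))
  carriers <- split$sample[split$group == "carrier"]
  rule_low <- colnames(co$expression)[co$expression["TGT", ] <=
                                        median(co$expression["TGT", ])]
  manual <- intersect(sprintf("P%03d", c(1:10, 11:18, 40:44)), rule_low)
  expect_setequal(carriers, manual)

  none <- surv_cohort(mut = list(ZZZ = 1:5), expr_genes = c("TGT", "ZZZ"))
  ints_none <- tibble::tibble(target = "TGT", partner = "A",
                              tissue = "lung", itype = "CSV")
  msplit <- module_carrier_split(none, build_module(ints_none, "TGT", "lung"),
                                 style = "carrier")
  expect_true(all(msplit$group == "non_carrier"))
  expect_true(attr(msplit, "degenerate"))
})

test_that("expression-style module split divides module mutants at the target median", {
  co <- surv_cohort(n = 60, mut = list(A = 1:12, B = 13:24),
                    expr_genes = c("TGT", "A", "B"))
  ints <- tibble::tibble(target = "TGT", partner = c("A", "B"),
                         tissue = "lung", itype = "CSL")
  mod <- build_module(ints, "TGT", "lung")
  sp <- module_carrier_split(co, mod, style = "expression")
  expect_equal(nrow(sp), 24)
  expect_equal(sum(sp$group == "target_low"), 12)
})

test_that("single-pair survival handles empty and one-sided subcohorts", {
  co <- surv_cohort()
  fit <- single_pair_survival(co, "TGT", "PRT")
  expect_false(fit$degenerate)
  expect_s3_class(fit$test, "crgi_test")
  expect_true(all(c("target_low", "target_high") %in% fit$km$group))
  g <- glance(fit)
  expect_equal(g$n.groups, 2)

  nomut <- surv_cohort(mut = list(OTHER = 1:10), expr_genes = c("TGT", "OTHER"))
  empty <- single_pair_survival(nomut, "TGT", "PRT")
  expect_true(empty$degenerate)
})

test_that("log-rank grouping is calibrated under label permutation", {
  set.seed(99)
  co <- surv_cohort(n = 100, mut = list(PRT = 1:40))
  rejections <- replicate(200, {
    samples <- cohort_samples(co)
    groups <- tibble::tibble(sample = samples,
                             group = sample(rep(c("a", "b"), 50)))
    fit <- compare_survival(co, groups)
    fit$test$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.105)
})
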