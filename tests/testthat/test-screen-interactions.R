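test_that("orientation normalisation flips essentiality screens and is idempotent", {
  m <- matrix(rnorm(6), 2, dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  lin <- setNames(rep("lung", 3), colnames(m))
  hi <- screen_dataset(m, lin, "hi", "high_is_viable")
  lo <- screen_dataset(m, lin, "lo", "low_is_viable")
  expect_equal(orient_to_viability(hi)$scores, m)
  expect_equal(orient_to_viability(lo)$scores, -m)
  expect_equal(orient_to_viability(lo)$orientation, "high_is_viable")
  expect_equal(orient_to_viability(orient_to_viability(lo)),
               orient_to_viability(lo))
})

test_that("tissues need more than three cell lines to be eligible", {
  m <- matrix(rnorm(7), 1, dimnames = list("g1", sprintf("c%d", 1:7)))
  lin <- setNames(c(rep("lung", 4), rep("breast", 3)), colnames(m))
  s <- screen_dataset(m, lin, "s", "high_is_viable")
  expect_equal(eligible_tissues(s), "lung")
  expect_setequal(eligible_tissues(s, min_lines = 1), c("lung", "breast"))
})

test_that("pair test splits target scores by partner alteration", {
  # 3 mutant lines clearly below 4 wild-type lines: exact one-sided p = 1/C(7,3)
  scr <- make_screen(list(TGT = c(-3, -2.5, -2, 0, 0.1, 0.2, 0.3),
                          OTHER = rnorm(7)))
  muts <- make_mutations(c("CL01", "CL02", "CL03"), "PRT")
  res <- test_pair(scr, muts, "lung", "TGT", "PRT")
  expect_true(res$tested)
  expect_equal(res$n_mut, 3)
  expect_equal(res$p_lethal, 1 / choose(7, 3))
  expect_gt(res$p_viable, 0.5)

  # one-sided p-values in the two directions cannot both be small
  set.seed(5)
  for (i in 1:20) {
    scr2 <- make_screen(list(TGT = rnorm(12), O = rnorm(12)))
    muts2 <- make_mutations(sprintf("CL%02d", 1:5), "PRT")
    r <- test_pair(scr2, muts2, "lung", "TGT", "PRT")
    expect_false(r$p_lethal < 0.5 && r$p_viable < 0.5)
  }

  small <- test_pair(scr, make_mutations("CL01", "PRT"), "lung", "TGT", "PRT")
  expect_false(small$tested)
  expect_equal(small$reason, "group_below_min")
  absent <- test_pair(scr, muts, "lung", "MISSING", "PRT")
  expect_false(absent$tested)
  expect_equal(absent$reason, "target_not_scored")
})

test_that("candidate scan filters on chromatin-regulator membership and alpha", {
  scr <- make_screen(list(TGT = c(-3, -2.5, -2, 0, 0.1, 0.2, 0.3),
                          OTH = c(4, 1, 5, 2, 6, 3, 7)))
  muts <- make_mutations(c("CL01", "CL02", "CL03"), "PRT")
  pairs <- tibble::tibble(target = c("TGT", "OTH"), partner = c("PRT", "PRT"))

  hits <- scan_candidates(list(scr), muts, cr_genes = "PRT", pairs = pairs)
  expect_equal(hits$target[hits$candidate], "TGT")
  expect_equal(hits$direction[hits$candidate], "CSL")

  # no chromatin regulator on either side: pair never tested
  none <- scan_candidates(list(scr), muts, cr_genes = "ZZZ", pairs = pairs,
                          keep_all = TRUE)
  expect_equal(nrow(none), 0)

  all_kept <- scan_candidates(list(scr), muts, cr_genes = "PRT", pairs = pairs,
                              alpha = 1)
  expect_true(all(all_kept$candidate[all_kept$tested]))
})

test_that("consensus requires two supporting screens and combines all tested p-values", {
  base <- tibble::tibble(tissue = "lung", target = "T", partner = "P",
                         n_mut = 10L, n_wt = 20L, tested = TRUE,
                         reason = NA_character_)
  cands <- dplyr::bind_rows(
    dplyr::mutate(base, screen = "s1", p_lethal = 0.01, p_viable = 0.995),
    dplyr::mutate(base, screen = "s2", p_lethal = 0.01, p_viable = 0.995)
  )
  recs <- consensus(cands)
  expect_equal(nrow(recs), 1)
  expect_equal(recs$itype, "CSL")
  expect_equal(recs$n_support, 2)
  expect_equal(length(recs$per_dataset_p[[1]]), 2)
  expect_equal(recs$combined_p,
               chisq_sf_even_df(-2 * sum(log(c(0.01, 0.01))), 4),
               tolerance = 1e-12)

  # significant in a single screen only: dropped
  solo <- dplyr::bind_rows(
    dplyr::mutate(base, screen = "s1", p_lethal = 0.01, p_viable = 0.995),
    dplyr::mutate(base, screen = "s2", p_lethal = 0.50, p_viable = 0.52)
  )
  expect_equal(nrow(consensus(solo)), 0)

  # opposing directions across screens: conflict record, not consensus
  conf <- dplyr::bind_rows(
    dplyr::mutate(base, screen = "s1", p_lethal = 0.01, p_viable = 0.995),
    dplyr::mutate(base, screen = "s2", p_lethal = 0.99, p_viable = 0.01),
    dplyr::mutate(base, screen = "s3", p_lethal = 0.02, p_viable = 0.97)
  )
  out <- consensus(conf)
  expect_true(all(out$conflict))
  expect_equal(nrow(consensus_records(out)), 0)
})

test_that("negating all viability scores swaps lethal and viable calls", {
  cfg <- sim_config(seed = 21, n_planted_csl = 4, n_planted_csv = 3,
                    n_null_partners = 10, n_genes = 60, n_cr = 20,
                    n_cell_lines = 60)
  scr <- generate_screens(cfg)
  pairs <- cfg$planted[, c("target", "partner")]
  fwd <- scan_candidates(scr$screens, scr$mutations, cfg$cr_genes,
                         pairs = pairs, keep_all = TRUE)
  flipped <- lapply(scr$screens, function(s) {
    s <- orient_to_viability(s)
    s$scores <- -s$scores
    s
  })
  rev <- scan_candidates(flipped, scr$mutations, cfg$cr_genes,
                         pairs = pairs, keep_all = TRUE)
  key <- c("screen", "target", "partner")
  merged <- dplyr::inner_join(fwd, rev, by = key, suffix = c("_f", "_r"))
  expect_equal(merged$p_lethal_f, merged$p_viable_r, tolerance = 1e-12)
  expect_equal(merged$p_viable_f, merged$p_lethal_r, tolerance = 1e-12)
  swapped <- dplyr::case_when(merged$direction_f == "CSL" ~ "CSV",
                              merged$direction_f == "CSV" ~ "CSL",
                              TRUE ~ merged$direction_f)
  expect_equal(merged$direction_r, swapped)
})
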