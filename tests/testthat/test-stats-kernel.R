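test_that("rank-sum test matches exact enumeration on small tie-free inputs", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6), "less")$p_value, 0.05)
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3), "less")$p_value, 1)
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "less")$p_value, 1 / 6)

  set.seed(101)
  for (i in 1:40) {
    n_x <- sample(1:6, 1); n_y <- sample(1:6, 1)
    vals <- sample(1:50, n_x + n_y)
    x <- vals[seq_len(n_x)]; y <- vals[-seq_len(n_x)]
    for (alt in c("less", "greater")) {
      expect_equal(rank_sum_test(x, y, alt)$p_value,
                   enum_rank_sum_p(x, y, alt), tolerance = 1e-12)
    }
  }
})

test_that("rank-sum approximation agrees with the reference implementation under ties", {
  set.seed(202)
  for (i in 1:30) {
    x <- sample(1:5, 20, replace = TRUE)
    y <- sample(1:5, 25, replace = TRUE)
    for (alt in c("less", "greater", "two.sided")) {
      ref <- suppressWarnings(
        wilcox.test(x, y, alternative = alt, exact = FALSE, correct = TRUE))
      expect_equal(rank_sum_test(x, y, alt)$p_value, ref$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("rank-sum handles degenerate and invalid input", {
  res <- rank_sum_test(c(2, 2, 2), c(2, 2), "less")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_error(rank_sum_test(numeric(0), 1:3), "empty")
})

test_that("rank-sum null calibration stays at the nominal level", {
  set.seed(303)
  rejections <- replicate(2000, {
    rank_sum_test(rnorm(15), rnorm(15), "less")$p_value < 0.05
  })
  ci <- qbinom(c(0.005, 0.995), 2000, 0.05)
  expect_gte(sum(rejections), ci[[1]])
  expect_lte(sum(rejections), ci[[2]])
})

test_that("Fisher combination matches the closed-form chi-square tail", {
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(0.2), 0.2)
  s <- -2 * sum(log(c(0.05, 0.05)))
  expect_equal(s, 11.98293, tolerance = 1e-6)
  expect_equal(fisher_combine(c(0.05, 0.05)), chisq_sf_even_df(s, 4),
               tolerance = 1e-14)
  expect_error(fisher_combine(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(fisher_combine(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("Fisher combination is monotone in each input", {
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(2:6, 1))
    j <- sample(length(p), 1)
    q <- p; q[j] <- p[j] * runif(1)
    expect_lte(fisher_combine(q), fisher_combine(p))
  }
})

test_that("BH adjustment reproduces the hand step-up procedure", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(1, 1)), c(1, 1))
  expect_identical(bh_adjust(numeric(0)), numeric(0))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_hand(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    # thresholding adjusted values selects the classical step-up set
    q <- 0.1
    m <- length(p)
    o <- order(p)
    k <- suppressWarnings(max(which(p[o] <= seq_len(m) / m * q)))
    stepup <- if (is.finite(k)) o[seq_len(k)] else integer(0)
    expect_setequal(which(adj <= q), stepup)
  }
})

test_that("hypergeometric tail equals direct pmf summation", {
  expect_equal(hypergeom_tail(0, 5, 5, 20), 1)
  expect_equal(hypergeom_tail(3, 3, 3, 10), 1 / 120)
  expect_equal(hypergeom_tail(1, 2, 2, 4), 5 / 6)
  expect_error(hypergeom_tail(4, 3, 3, 10), "inconsistent")
  expect_error(hypergeom_tail(1, 12, 3, 10), "inconsistent")
})

test_that("Pearson correlation matches the direct formula", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_cor(x, x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  res <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  degen <- pearson_cor(c(1, 1, 1), c(1, 2, 3))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$r))
})

test_that("Welch t test handles planted and degenerate cases", {
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  zv <- two_sample_t(c(0, 0), c(1, 1))
  expect_true(zv$degenerate)
  expect_lt(zv$p_value, 1e-100)
  res <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.2247449, tolerance = 1e-6)
  expect_error(two_sample_t(1, c(1, 2)), "fewer than 2")
})

test_that("2x2 chi-square matches the closed-form statistic", {
  ind <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  expect_equal(chi_square_2x2(20, 10, 10, 20)$statistic, 20 / 3)
  expect_equal(chi_square_2x2(1, 0, 0, 1)$statistic, 2)
  expect_error(chi_square_2x2(0, 0, 3, 4), "zero margin")
})

test_that("Kaplan-Meier curve reproduces hand-computed product limits", {
  fit <- km_curve(1:4, rep(1, 4))
  expect_equal(fit$surv, c(0.75, 0.5, 0.25, 0))
  cens <- km_curve(1:4, rep(0, 4))
  expect_true(all(cens$surv == 1))
  mixed <- km_curve(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(km_surv_at(mixed, c(1, 2, 3)), c(0.75, 0.5, 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
  # the curve reaches zero when the last observed time is an event,
  # and stays positive when follow-up ends in censoring
  full <- km_curve(c(3, 1, 2), c(1, 1, 1))
  expect_equal(min(full$surv), 0)
  part <- km_curve(c(3, 1, 2), c(0, 1, 1))
  expect_equal(min(part$surv), 1 / 3)
})

test_that("log-rank test handles identical, censored-only and 3-group input", {
  d <- tibble::tibble(time = rep(c(1, 2, 3), 2), event = rep(1, 6),
                      group = rep(c("a", "b"), each = 3))
  res <- logrank_test(d)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  nocens <- tibble::tibble(time = c(1, 1, 2, 2), event = 0,
                           group = c("a", "a", "b", "b"))
  degen <- logrank_test(nocens)
  expect_true(degen$degenerate)
  expect_equal(degen$p_value, 1)

  three <- tibble::tibble(
    time = c(1, 2, 3, 2, 3, 4, 5, 6, 7),
    event = c(1, 1, 1, 1, 1, 1, 0, 0, 0),
    group = rep(c("a", "b", "c"), each = 3))
  res3 <- logrank_test(three)
  expect_equal(res3$df, 2)
  expect_false(res3$degenerate)
})

test_that("log-rank p agrees with a label-permutation reference", {
  set.seed(77)
  d <- tibble::tibble(
    time = c(rexp(12, 1), rexp(12, 2.2)),
    event = rbinom(24, 1, 0.85),
    group = rep(c("a", "b"), each = 12))
  obs <- logrank_test(d)
  perm <- replicate(1000, {
    d2 <- d; d2$group <- sample(d2$group)
    logrank_test(d2)$statistic
  })
  p_perm <- mean(perm >= obs$statistic)
  # Monte-Carlo error at 1000 shuffles
  expect_lt(abs(p_perm - obs$p_value),
            3 * sqrt(obs$p_value * (1 - obs$p_value) / 1000) + 0.02)
})
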