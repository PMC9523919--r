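# Shared floor applied to p-values before log transforms.
P_FLOOR <- 1e-300

new_test_result <- function(statistic, p_value, alternative, n_x, n_y,
                            method, degenerate = FALSE) {
  out <- tibble::tibble(
    statistic = as.numeric(statistic),
    p_value = min(max(as.numeric(p_value), P_FLOOR), 1),
    alternative = alternative,
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    method = method, degenerate = degenerate
  )
  class(out) <- c("crgi_test", class(out))
  out
}

#' Wilcoxon rank-sum test with a deterministic exact/approximate switch
#'
#' Mid-ranks are used for ties. The p-value is exact (by enumeration of the
#' rank-sum distribution) when `length(x) + length(y) <= 12` and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. `alternative = "less"` means the `x`
#' group tends lower.
#'
#' @param x,y Numeric vectors (both non-empty; `NA` dropped).
#' @param alternative `"less"`, `"greater"`, or `"two.sided"`.
#' @return One-row tibble of class `crgi_test` with columns `statistic`
#'   (the Mann-Whitney U of `x`), `p_value`, `alternative`, `n_x`, `n_y`,
#'   `method`, `degenerate`.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two.sided")) {
  alternative <- match.arg(alternative)
  core <- rank_sum_core(x, y, alternative)
  new_test_result(core$statistic, core$p_value, alternative,
                  core$n_x, core$n_y, core$method, core$degenerate)
}

# Tibble-free core used by the per-feature / per-pair hot loops.
rank_sum_core <- function(x, y, alternative) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n_x <- length(x); n_y <- length(y)
  if (n_x == 0 || n_y == 0) abort("rank_sum_test: empty group")
  all_vals <- c(x, y)
  if (all(all_vals == all_vals[[1]])) {
    return(list(statistic = n_x * n_y / 2, p_value = 1, n_x = n_x, n_y = n_y,
                method = "wilcoxon", degenerate = TRUE))
  }
  r <- rank(all_vals)
  # tie sizes via min-ranks: each tied block contributes its size at one index
  tie_sizes <- tabulate(rank(all_vals, ties.method = "min"))
  has_ties <- any(tie_sizes > 1)
  u <- sum(r[seq_len(n_x)]) - n_x * (n_x + 1) / 2   # Mann-Whitney U of x
  if (n_x + n_y <= 12 && !has_ties) {
    p <- switch(alternative,
      less = stats::pwilcox(u, n_x, n_y),
      greater = stats::pwilcox(u - 1, n_x, n_y, lower.tail = FALSE),
      two.sided = {
        if (u > n_x * n_y / 2) {
          min(1, 2 * stats::pwilcox(u - 1, n_x, n_y, lower.tail = FALSE))
        } else {
          min(1, 2 * stats::pwilcox(u, n_x, n_y))
        }
      })
    method <- "wilcoxon-exact"
  } else {
    # normal approximation with tie correction and continuity correction
    n <- n_x + n_y
    mu <- n_x * n_y / 2
    tie_term <- sum(tie_sizes^3 - tie_sizes)
    sigma2 <- n_x * n_y / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    z <- u - mu
    p <- switch(alternative,
      less = stats::pnorm((z + 0.5) / sigma),
      greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
      two.sided = {
        zz <- (z - sign(z) * 0.5) / sigma
        min(1, 2 * stats::pnorm(-abs(zz)))
      })
    method <- "wilcoxon-normal"
  }
  list(statistic = u, p_value = max(min(p, 1), P_FLOOR), n_x = n_x, n_y = n_y,
       method = method, degenerate = FALSE)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via the statistic \eqn{-2 \sum \ln p_i},
#' referred to a chi-square distribution with \eqn{2k} degrees of freedom.
#' A single p-value is returned unchanged. Inputs are floored at 1e-300
#' before the log transform.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Combined upper-tail probability (scalar in (0, 1]).
#' @export
fisher_combine <- function(pvalues) {
  if (length(pvalues) == 0) abort("fisher_combine: empty input")
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("fisher_combine: p-values must lie in (0, 1]")
  }
  if (length(pvalues) == 1) return(pvalues[[1]])
  stat <- -2 * sum(log(pmax(pvalues, P_FLOOR)))
  max(pchisq(stat, df = 2 * length(pvalues), lower.tail = FALSE), P_FLOOR)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues Numeric vector in (0, 1]; may be empty.
#' @return Adjusted p-values in the original order, clipped to 1.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    abort("bh_adjust: p-values must lie in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Upper-tail hypergeometric probability
#'
#' Probability of observing at least `k` successes when drawing `n` items
#' without replacement from a population of `N` containing `K` successes.
#' Computed in log space by `phyper`.
#'
#' @param k Observed overlap (0 <= k <= min(K, n)).
#' @param K Number of successes in the population.
#' @param n Number of draws.
#' @param N Population size.
#' @return P(X >= k), a scalar in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n)) {
    abort("hypergeom_tail: inconsistent counts")
  }
  if (k == 0) return(1)
  max(phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE), P_FLOOR)
}

#' Pearson correlation with a two-sided p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete pairs).
#' @return One-row tibble: `r`, `p_value`, `n`, `degenerate`. Zero variance
#'   in either vector yields `r = NA` with `degenerate = TRUE` so callers
#'   can exclude the pair.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) abort("pearson_cor: unequal lengths")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("pearson_cor: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = n, degenerate = TRUE))
  }
  res <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(res$estimate),
                 p_value = min(max(res$p.value, P_FLOOR), 1),
                 n = n, degenerate = FALSE)
}

#' Welch two-sample t test (two-sided)
#'
#' Unequal-variance form. When both groups have zero variance the result is
#' flagged degenerate: equal means give statistic 0 and p = 1, unequal means
#' give an infinite statistic with the p-value floored at 1e-300.
#'
#' @param x,y Numeric vectors, each with >= 2 values.
#' @return One-row tibble of class `crgi_test`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("two_sample_t: group with fewer than 2 values")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(new_test_result(0, 1, "two.sided", length(x), length(y),
                             "welch-t", degenerate = TRUE))
    }
    return(new_test_result(sign(mean(x) - mean(y)) * Inf, P_FLOOR, "two.sided",
                           length(x), length(y), "welch-t", degenerate = TRUE))
  }
  res <- t.test(x, y, var.equal = FALSE, alternative = "two.sided")
  new_test_result(unname(res$statistic), res$p.value, "two.sided",
                  length(x), length(y), "welch-t")
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction; 1 degree of freedom; two-sided p.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` on top, `(c, d)` below.
#' @return One-row tibble of class `crgi_test`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("chi_square_2x2: negative count")
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("chi_square_2x2: zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  new_test_result(stat, pchisq(stat, df = 1, lower.tail = FALSE),
                  "two.sided", a + b, c + d, "chi-square",
                  degenerate = stat == 0 && n == 0)
}

#' Kaplan-Meier product-limit curve
#'
#' @param times Non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @return Tibble of class `crgi_km`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv` — the right-continuous survival estimate after each
#'   observed time.
#' @export
km_curve <- function(times, events) {
  if (length(times) != length(events)) abort("km_curve: unequal lengths")
  if (any(times < 0)) abort("km_curve: negative time")
  if (!all(events %in% c(0, 1))) abort("km_curve: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  class(out) <- c("crgi_km", class(out))
  out
}

#' Survival probability at given times from a KM curve
#' @param km A [km_curve()] result.
#' @param t Times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  vapply(t, function(tt) {
    idx <- which(km$time <= tt & km$n_event > 0)
    if (length(idx) == 0) 1 else km$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test across two or more groups
#'
#' Standard observed-minus-expected chi-square over the shared event times,
#' with `length(unique(group)) - 1` degrees of freedom. With no events
#' anywhere the result is degenerate with p = 1.
#'
#' @param data Data frame with columns `time`, `event`, `group`.
#' @return One-row tibble of class `crgi_test` (an extra `df` column gives
#'   the degrees of freedom).
#' @export
logrank_test <- function(data) {
  if (!all(c("time", "event", "group") %in% names(data))) {
    abort("logrank_test: data needs columns time, event, group")
  }
  groups <- unique(data$group)
  if (length(groups) < 2) abort("logrank_test: need >= 2 groups")
  if (any(table(data$group) == 0)) abort("logrank_test: empty group")
  df <- length(groups) - 1
  if (sum(data$event) == 0) {
    out <- new_test_result(0, 1, "two.sided",
                           sum(data$group == groups[[1]]),
                           sum(data$group != groups[[1]]),
                           "log-rank", degenerate = TRUE)
    out$df <- df
    return(out)
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = data)
  stat <- fit$chisq
  out <- new_test_result(stat, pchisq(stat, df = df, lower.tail = FALSE),
                         "two.sided",
                         sum(data$group == groups[[1]]),
                         sum(data$group != groups[[1]]),
                         "log-rank")
  out$df <- df
  out
}
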