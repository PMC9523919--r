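# Independent brute-force oracles used to freeze expected values.

# Exact rank-sum p by enumerating all C(n, n_x) assignments of the pooled
# ranks to the x group (tie-free inputs only).
enum_rank_sum_p <- function(x, y, alternative) {
  n_x <- length(x)
  pooled <- c(x, y)
  stopifnot(!any(duplicated(pooled)))
  r <- rank(pooled)
  obs <- sum(r[seq_len(n_x)])
  sets <- utils::combn(length(pooled), n_x)
  sums <- apply(sets, 2, function(idx) sum(r[idx]))
  switch(alternative,
         less = mean(sums <= obs),
         greater = mean(sums >= obs),
         two.sided = min(1, 2 * min(mean(sums <= obs), mean(sums >= obs))))
}

# Upper-tail hypergeometric probability by direct summation of the pmf.
enum_hyper_tail <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Chi-square survival function for even df, closed form:
# P(X > s) = exp(-s/2) * sum_{j=0}^{df/2-1} (s/2)^j / j!
chisq_sf_even_df <- function(s, df) {
  stopifnot(df %% 2 == 0)
  j <- 0:(df / 2 - 1)
  exp(-s / 2) * sum(exp(j * log(s / 2) - lgamma(j + 1)))
}

# Hand-executed BH step-up procedure.
bh_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Tiny single-tissue screen over explicit per-gene score vectors.
make_screen <- function(scores_list, name = "s1",
                        orientation = "high_is_viable", tissue = "lung") {
  lines <- sprintf("CL%02d", seq_along(scores_list[[1]]))
  mat <- do.call(rbind, scores_list)
  dimnames(mat) <- list(names(scores_list), lines)
  screen_dataset(mat, setNames(rep(tissue, length(lines)), lines),
                 name, orientation)
}

make_mutations <- function(samples, gene, class = "missense") {
  mutation_catalog(tibble::tibble(sample = samples, gene = gene,
                                  mutation_class = class))
}
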