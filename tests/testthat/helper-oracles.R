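# Independent oracles used across tests.

# Exhaustive one-sided Fisher p: sum of combinatorial point masses of all
# margin-consistent 2x2 tables at least as extreme (tp' >= tp). Uses only
# choose(), independently of the hypergeometric-tail implementation.
fisher_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  n_pos <- tp + fn
  k <- tp + fp
  if (k == 0) return(1)
  lo <- max(0, k - (n - n_pos))
  hi <- min(k, n_pos)
  mass <- function(x) choose(n_pos, x) * choose(n - n_pos, k - x) / choose(n, k)
  sum(vapply(seq(lo, hi)[seq(lo, hi) >= tp], mass, numeric(1)))
}

cc <- function(tp, fp, fn, tn) list(tp = tp, fp = fp, fn = fn, tn = tn)

# Brute-force majority vote: per compound, count votes with table().
vote_oracle <- function(members) {
  m <- length(members)
  vapply(seq_along(members[[1]]), function(i) {
    votes <- vapply(members, `[[`, numeric(1), i)
    ones <- sum(votes == 1)
    zeros <- m - ones
    if (ones > zeros) 1L else if (zeros > ones) 0L else 1L  # tie -> positive
  }, integer(1))
}

# Small planted-signal feature dataset for model tests.
planted_feature_data <- function(n = 300, seed = 101) {
  spec <- synthetic_spec(
    n, 0.7,
    planted = list(list(name = "a", prev_pos = 0.5, prev_neg = 0.05),
                   list(name = "b", prev_pos = 0.4, prev_neg = 0.05)),
    n_noise_features = 20, seed = seed)
  generate_feature_dataset(spec)
}
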