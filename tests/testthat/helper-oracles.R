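# Independent oracles, deliberately written with naive loops so they share
# no code path with the package implementation.

# Brute-force open-bigram set: every ordered pair (i < j) with at most
# `max_gap` intervening letters, de-duplicated, plus edge pairs on request.
oracle_ob_set <- function(word, max_gap = Inf, edges = FALSE) {
  l <- strsplit(toupper(word), "", fixed = TRUE)[[1L]]
  n <- length(l)
  out <- character(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (j - i - 1L <= max_gap) out <- c(out, paste0(l[i], l[j]))
      }
    }
  }
  if (edges) out <- c(out, paste0("#", l[1L]), paste0(l[n], "#"))
  unique(out)
}

# Brute-force binary match: shared pairs over target pairs.
oracle_binary_match <- function(prime, target, max_gap = Inf, edges = FALSE) {
  ps <- oracle_ob_set(prime, max_gap, edges)
  ts <- oracle_ob_set(target, max_gap, edges)
  length(intersect(ps, ts)) / length(ts)
}

# Monte-Carlo activation map under Gaussian positional noise: sample
# perceived positions and estimate the order probability empirically.
oracle_noisy_acts_mc <- function(word, sigma, gap_weights = c(1, 0.8, 0.4),
                                 max_gap = 2, n_draws = 2e5) {
  l <- strsplit(toupper(word), "", fixed = TRUE)[[1L]]
  n <- length(l)
  acts <- numeric(0)
  bump <- function(acts, pair, v) {
    acts[pair] <- max(acts[pair], v, 0, na.rm = TRUE)
    acts
  }
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      if (j == i) next
      g <- j - i - 1L
      if (g > max_gap) next
      w <- if (g + 1L <= length(gap_weights)) gap_weights[g + 1L] else 0
      if (w == 0) next
      p <- mean(stats::rnorm(n_draws, i, sigma) < stats::rnorm(n_draws, j, sigma))
      acts <- bump(acts, paste0(l[i], l[j]), w * p)
      acts <- bump(acts, paste0(l[j], l[i]), w * (1 - p))
    }
  }
  acts[acts > 0]
}

# Monte-Carlo noisy match score: min-overlap of the sampled activation
# maps, normalized by the target total.
oracle_noisy_match_mc <- function(prime, target, sigma,
                                  gap_weights = c(1, 0.8, 0.4), max_gap = 2,
                                  n_draws = 2e5) {
  pa <- oracle_noisy_acts_mc(prime, sigma, gap_weights, max_gap, n_draws)
  ta <- oracle_noisy_acts_mc(target, sigma, gap_weights, max_gap, n_draws)
  shared <- intersect(names(pa), names(ta))
  sum(pmin(pa[shared], ta[shared])) / sum(ta)
}

# Deterministic sigma grid-search oracle for the noise calibration.
oracle_sigma_grid <- function(target_scores, step = 0.01, max_sigma = 3) {
  grid <- seq(step, max_sigma, by = step)
  sse <- vapply(grid, function(s) {
    pol <- policy_seriol(noise_sd = s)
    fit <- vapply(seq_len(nrow(target_scores)), function(k) {
      noisy_ob_match(target_scores$prime[k], target_scores$target[k], pol)$score
    }, numeric(1))
    sum((target_scores$score - fit)^2)
  }, numeric(1))
  list(sigma = grid[which.min(sse)], sse = min(sse))
}
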