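# Prime-target match scores under competing letter-order coding schemes.
#
# Every score is normalized by the target's code (count or weight sum), so
# that an identity prime scores 1 under every model and a prime whose code
# is a superset of the target's also scores 1. All scores lie in [0,1]; a
# prime sharing no letters with the target scores 0 under every model.

match_result <- function(prime, target, score, shared, model, policy = NULL) {
  structure(
    list(prime = prime$text, target = target$text, score = score,
         shared = shared, model = model, policy = policy),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s -> %s  [%s]  M = %.4f\n",
              tolower(x$prime), x$target, x$model, x$score))
  if (length(x$shared)) cat("  shared:", paste(x$shared, collapse = " "), "\n")
  invisible(x)
}

#' Binary open-bigram match score
#'
#' The number of open bigrams shared by prime and target divided by the
#' number of open bigrams in the target. Comparison is case-insensitive
#' (the task is cross-case). The shared set is returned for inspection.
#'
#' @param prime,target Letter strings (or raw character scalars).
#' @param policy A [coding_policy()] applied to both strings.
#' @return A `match_result` with `score` in `[0,1]` and `shared`, the
#'   character vector of shared pairs.
#' @examples
#' binary_ob_match("jugde", "JUDGE", policy_unbounded())$score  # 0.9
#' binary_ob_match("casaca", "CASA", coding_policy(max_gap = 2))$score  # 1
#' @export
binary_ob_match <- function(prime, target, policy = coding_policy()) {
  prime <- as_letter_string(prime); target <- as_letter_string(target)
  pc <- extract_open_bigrams(prime, policy)
  tc <- extract_open_bigrams(target, policy)
  if (nrow(tc) == 0L) {
    stop(sprintf("target '%s' has no open bigrams under this policy; score undefined",
                 target$text))
  }
  shared <- intersect(pc$pair, tc$pair)
  match_result(prime, target, length(shared) / nrow(tc), sort(shared),
               "binary_ob", policy)
}

#' Distance-weighted open-bigram match score
#'
#' Pairs are weighted by the number of letters their members span (defaults:
#' adjacent 1.0, one intervening letter 0.8, two 0.4, three or more 0). The
#' score is the summed weight of shared pairs divided by the summed weight of
#' the target's pairs. A shared pair contributes the smaller of its prime and
#' target weights, which makes this the exact noiseless limit of
#' [noisy_ob_match()]; for the prime types used in masked-priming designs
#' (two-letter, transposed-letter, substituted-letter primes) the prime's
#' occurrence is never more distant than the target's, so this coincides
#' with weighting by the target gap alone.
#'
#' @inheritParams binary_ob_match
#' @param policy A [coding_policy()] with `gap_weights` defined; defaults to
#'   [policy_seriol()].
#' @return A `match_result`.
#' @examples
#' weighted_ob_match("bo", "ABOLISH")$score  # 1.0 / 11.6
#' weighted_ob_match("bs", "ABOLISH")$score  # 0: the pair spans three letters
#' @export
weighted_ob_match <- function(prime, target, policy = policy_seriol()) {
  prime <- as_letter_string(prime); target <- as_letter_string(target)
  if (is.null(policy$gap_weights)) policy <- policy_seriol(policy$include_edges)
  pc <- extract_open_bigrams(prime, policy)
  tc <- extract_open_bigrams(target, policy)
  denom <- sum(tc$weight)
  if (denom <= 0) {
    stop(sprintf("target '%s' has zero total bigram weight; score undefined",
                 target$text))
  }
  shared <- intersect(pc$pair, tc$pair)
  num <- sum(pmin(pc$weight[match(shared, pc$pair)],
                  tc$weight[match(shared, tc$pair)]))
  match_result(prime, target, num / denom, sort(shared), "weighted_ob", policy)
}

# Open-bigram activations under Gaussian positional noise.
#
# Each letter's perceived position is Gaussian with mean equal to its index
# and SD sigma. For letters at positions i < j the canonical pair is active
# with probability P(perceived i < perceived j) = pnorm((j - i) / (sigma *
# sqrt(2))) and the reversed pair with the complementary probability; both
# are multiplied by the gap weight of the physical separation. Repeated
# pairs collapse to their maximum activation. At sigma = 0 reversed pairs
# have activation 0 and the code reduces to the noiseless weighted code.
noisy_bigram_activations <- function(s, policy) {
  s <- as_letter_string(s)
  sigma <- policy$noise_sd
  n <- s$n
  pair <- character(0); act <- numeric(0)
  if (n >= 2L) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- ij[, 1L]; j <- ij[, 2L]
    g <- j - i - 1L
    keep <- g <= policy$max_gap
    i <- i[keep]; j <- j[keep]; g <- g[keep]
    w <- weight_for_gap(policy, g)
    if (sigma > 0) {
      # lower tail computed directly: 1 - pnorm(x) underflows to 0 long
      # before pnorm(-x) does, and the reversed activation must stay
      # strictly positive for any sigma > 0
      p_canon <- stats::pnorm((j - i) / (sigma * sqrt(2)))
      p_rev <- stats::pnorm(-(j - i) / (sigma * sqrt(2)))
    } else {
      p_canon <- rep(1, length(i))
      p_rev <- rep(0, length(i))
    }
    pair <- c(paste0(s$letters[i], s$letters[j]),
              paste0(s$letters[j], s$letters[i]))
    act <- c(w * p_canon, w * p_rev)
  }
  if (policy$include_edges) {
    pair <- c(pair, paste0("#", s$letters[1L]), paste0(s$letters[n], "#"))
    act <- c(act, 1, 1)
  }
  keep <- act > 0
  pair <- pair[keep]; act <- act[keep]
  if (length(pair)) {
    ord <- order(pair, -act)
    pair <- pair[ord]; act <- act[ord]
    dup <- duplicated(pair)
    pair <- pair[!dup]; act <- act[!dup]
  }
  data.frame(pair = pair, activation = act, stringsAsFactors = FALSE)
}

#' Noisy-position open-bigram match score
#'
#' Letter positions are perceived with Gaussian noise (SD `noise_sd` of the
#' policy, in letter-position units), so a reversed pair has a small but
#' nonzero activation that grows with the noise. A pair's activation is the
#' probability of perceiving its letters in that order times the gap weight
#' of their physical separation. The match score is the overlap of the two
#' activation maps — shared pairs contribute `min(prime, target)` activation
#' — normalized by the target's total activation. With `noise_sd = 0` this
#' reduces exactly to [weighted_ob_match()].
#'
#' @inheritParams binary_ob_match
#' @param policy A [coding_policy()]; `noise_sd` gives the positional noise.
#'   Defaults to the distance-weighted policy with `noise_sd = 0.5`.
#' @return A `match_result`.
#' @examples
#' noisy_ob_match("fo", "OF")$score   # small but positive
#' noisy_ob_match("of", "OF")$score   # 1
#' @export
noisy_ob_match <- function(prime, target, policy = policy_seriol(noise_sd = 0.5)) {
  prime <- as_letter_string(prime); target <- as_letter_string(target)
  if (is.null(policy$gap_weights))
    policy <- coding_policy(policy$max_gap, policy$include_edges,
                            gap_weights = policy_seriol()$gap_weights,
                            noise_sd = policy$noise_sd)
  pa <- noisy_bigram_activations(prime, policy)
  ta <- noisy_bigram_activations(target, policy)
  denom <- sum(ta$activation)
  if (denom <= 0) {
    stop(sprintf("target '%s' has zero total bigram activation; score undefined",
                 target$text))
  }
  shared <- intersect(pa$pair, ta$pair)
  num <- sum(pmin(pa$activation[match(shared, pa$pair)],
                  ta$activation[match(shared, ta$pair)]))
  match_result(prime, target, num / denom, sort(shared), "noisy_ob", policy)
}

#' Calibrate the positional-noise width against published match scores
#'
#' One-dimensional least-squares fit of the noise SD so that
#' [noisy_ob_match()] scores best reproduce a set of published
#' (prime, target, score) triples. Published values from other
#' parameterizations are generally not exactly reproducible, so the fit
#' reports residuals rather than asserting agreement.
#'
#' @param target_scores A data frame with columns `prime`, `target`, `score`
#'   (published score in `[0,1]`); at least one row.
#' @param policy Base [coding_policy()]; its `noise_sd` is ignored.
#' @param interval Search interval for sigma, default `c(1e-4, 3)`.
#' @return A list with `sigma` (the least-squares estimate), `fitted`,
#'   `residuals` (published minus fitted), `sse`, and `interval`.
#' @export
calibrate_noise <- function(target_scores, policy = policy_seriol(),
                            interval = c(1e-4, 3)) {
  if (is.null(target_scores) || nrow(as.data.frame(target_scores)) == 0L) {
    stop("calibrate_noise requires at least one published score")
  }
  ts <- as.data.frame(target_scores)
  stopifnot(all(c("prime", "target", "score") %in% names(ts)),
            all(ts$score >= 0), all(ts$score <= 1))
  score_at <- function(sigma) {
    pol <- coding_policy(policy$max_gap, policy$include_edges,
                         gap_weights = policy$gap_weights, noise_sd = sigma)
    vapply(seq_len(nrow(ts)), function(k) {
      noisy_ob_match(ts$prime[k], ts$target[k], pol)$score
    }, numeric(1))
  }
  sse <- function(sigma) sum((ts$score - score_at(sigma))^2)
  opt <- stats::optimize(sse, interval = interval)
  fitted <- score_at(opt$minimum)
  list(sigma = opt$minimum, fitted = fitted,
       residuals = ts$score - fitted, sse = opt$objective,
       interval = interval)
}

#' Slot-coding match score
#'
#' Under slot coding every letter is bound to its absolute serial position,
#' so similarity is the number of positions holding identical letters
#' (strings left-aligned), divided by the target length. Transposing two
#' letters or substituting them costs the same two slots, which is why slot
#' coding predicts equal priming from transposed-letter and
#' substituted-letter primes.
#'
#' @inheritParams binary_ob_match
#' @return A `match_result`; `shared` lists the matching letters tagged with
#'   their positions.
#' @examples
#' slot_coding_match("jugde", "JUDGE")$score  # 3/5
#' slot_coding_match("junpe", "JUDGE")$score  # 3/5, same as the TL prime
#' @export
slot_coding_match <- function(prime, target) {
  prime <- as_letter_string(prime); target <- as_letter_string(target)
  k <- min(prime$n, target$n)
  hit <- which(prime$letters[seq_len(k)] == target$letters[seq_len(k)])
  match_result(prime, target, length(hit) / target$n,
               paste0(target$letters[hit], hit), "slot", NULL)
}

#' Simplified spatial-gradient match score
#'
#' A stand-in for gradient (spatial) coding of letter order: each string is
#' mapped to a per-letter activation decreasing geometrically with position
#' (`decay^(position - 1)`), so the first letter is most active. The score
#' sums, over letters present in both strings, the overlap
#' `min(prime activation, target activation)`, normalized by the target's
#' total activation. A letter absent from the prime contributes nothing, so
#' an all-letters-different prime scores 0. This is a deliberately
#' simplified gradient coder, not a full spatial-coding match.
#'
#' @inheritParams binary_ob_match
#' @param decay Geometric decay per position, in `(0,1)`; default 0.7.
#' @return A `match_result`; `shared` lists the overlapping letters.
#' @examples
#' gradient_match("bo", "ABOLISH")$score >= gradient_match("bs", "ABOLISH")$score
#' @export
gradient_match <- function(prime, target, decay = 0.7) {
  stopifnot(length(decay) == 1L, decay > 0, decay < 1)
  prime <- as_letter_string(prime); target <- as_letter_string(target)
  grad <- function(s) {
    a <- decay^(seq_len(s$n) - 1)
    # repeated letters keep their strongest (earliest) activation
    tapply(a, s$letters, max)
  }
  gp <- grad(prime); gt <- grad(target)
  shared <- intersect(names(gp), names(gt))
  num <- sum(pmin(gp[shared], gt[shared]))
  match_result(prime, target, num / sum(gt), sort(shared), "gradient", NULL)
}

#' Score a prime-target pair under one or several models
#'
#' Convenience dispatcher used by the batch interfaces. Model names:
#' `"binary"`, `"weighted"`, `"noisy"`, `"slot"`, `"gradient"`.
#'
#' @param prime,target Letter strings or character scalars.
#' @param models Character vector of model names.
#' @param policies Named list of [coding_policy()] objects keyed by model
#'   name; missing entries use each model's default.
#' @param decay Decay for the gradient model.
#' @return Named numeric vector of scores.
#' @export
score_pair <- function(prime, target,
                       models = c("binary", "weighted", "noisy", "slot", "gradient"),
                       policies = list(), decay = 0.7) {
  models <- match.arg(models, several.ok = TRUE)
  vapply(models, function(m) {
    switch(m,
      binary = binary_ob_match(prime, target,
                 policies$binary %||% coding_policy())$score,
      weighted = weighted_ob_match(prime, target,
                 policies$weighted %||% policy_seriol())$score,
      noisy = noisy_ob_match(prime, target,
                 policies$noisy %||% policy_seriol(noise_sd = 0.5))$score,
      slot = slot_coding_match(prime, target)$score,
      gradient = gradient_match(prime, target, decay)$score)
  }, numeric(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
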