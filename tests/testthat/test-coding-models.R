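seriol_denom_7 <- 6 * 1.0 + 5 * 0.8 + 4 * 0.4  # 11.6, ABOLISH-sized target

test_that("binary match reproduces the worked examples", {
  expect_equal(binary_ob_match("jugde", "JUDGE", policy_unbounded())$score, 0.9)
  expect_equal(binary_ob_match("junpe", "JUDGE", policy_unbounded())$score, 0.3)
  expect_setequal(binary_ob_match("junpe", "JUDGE", policy_unbounded())$shared,
                  c("JU", "JE", "UE"))
  # degenerate repeated-letter case: the longer prime fully contains the target code
  expect_equal(binary_ob_match("casaca", "CASA", coding_policy(max_gap = 2))$score, 1.0)
  expect_equal(binary_ob_match("casaca", "CASA",
                               coding_policy(max_gap = 2, include_edges = TRUE))$score, 1.0)
  expect_equal(binary_ob_match("fo", "OF")$score, 0)
  expect_equal(binary_ob_match("judge", "JUDGE", policy_unbounded())$score, 1)
  expect_error(binary_ob_match("ab", "A"), "undefined")
})

test_that("binary match equals the brute-force oracle on random pairs", {
  set.seed(41)
  for (k in 1:60) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    prime <- random_lexicon(1, n1)
    target <- random_lexicon(1, n2)
    for (g in list(2, Inf)) {
      expect_equal(binary_ob_match(prime, target, coding_policy(max_gap = g))$score,
                   oracle_binary_match(prime, target, max_gap = g))
    }
  }
})

test_that("distance-weighted match reproduces the derived values", {
  expect_equal(weighted_ob_match("bo", "ABOLISH")$score, 1.0 / seriol_denom_7)
  expect_equal(weighted_ob_match("bl", "ABOLISH")$score, 0.8 / seriol_denom_7)
  expect_equal(weighted_ob_match("bs", "ABOLISH")$score, 0)  # gap 3 weighs 0
  expect_equal(weighted_ob_match("abolish", "ABOLISH")$score, 1)
  expect_equal(weighted_ob_match("sb", "ABOLISH")$score, 0)
})

test_that("noisy match reduces to the weighted match as sigma -> 0", {
  pairs <- list(c("jugde", "JUDGE"), c("bo", "ABOLISH"), c("bl", "ABOLISH"),
                c("bs", "ABOLISH"), c("fo", "OF"), c("hte", "THE"),
                c("casaca", "CASA"), c("junpe", "JUDGE"))
  for (p in pairs) {
    w <- weighted_ob_match(p[1], p[2])$score
    nz <- noisy_ob_match(p[1], p[2], policy_seriol(noise_sd = 1e-4))$score
    n0 <- noisy_ob_match(p[1], p[2], policy_seriol(noise_sd = 0))$score
    expect_equal(nz, w, tolerance = 1e-6)
    expect_identical(n0, w)
  }
})

test_that("noisy match agrees with the Monte-Carlo position-sampling oracle", {
  set.seed(51)
  cases <- list(c("fo", "OF"), c("ob", "ABOLISH"), c("jugde", "JUDGE"))
  for (p in cases) {
    got <- noisy_ob_match(p[1], p[2], policy_seriol(noise_sd = 0.5))$score
    mc <- oracle_noisy_match_mc(p[1], p[2], sigma = 0.5)
    # per-pair MC standard error is ~0.5/sqrt(2e5); 0.01 is > 3 SE after
    # propagation through the normalized sum
    expect_equal(got, mc, tolerance = 0.01)
  }
})

test_that("reversed bigram prime scores strictly between 0 and the canonical prime", {
  rev_score <- noisy_ob_match("fo", "OF", policy_seriol(noise_sd = 0.5))$score
  can_score <- noisy_ob_match("of", "OF", policy_seriol(noise_sd = 0.5))$score
  expect_gt(rev_score, 0)
  expect_lt(rev_score, can_score)
  # gap-3 pairs carry weight 0 under the default distance weights, so both
  # orders score 0 regardless of noise
  expect_equal(noisy_ob_match("bs", "ABOLISH", policy_seriol(noise_sd = 0.5))$score, 0)
  expect_equal(noisy_ob_match("sb", "ABOLISH", policy_seriol(noise_sd = 0.5))$score, 0)
})

test_that("reversed-pair activation rises and canonical falls with sigma", {
  sigmas <- c(0.1, 0.25, 0.5, 1, 2)
  rev_act <- can_act <- numeric(length(sigmas))
  for (k in seq_along(sigmas)) {
    acts <- orthoprime:::noisy_bigram_activations(
      normalize_string("OF"), policy_seriol(noise_sd = sigmas[k]))
    can_act[k] <- acts$activation[acts$pair == "OF"]
    rev_act[k] <- acts$activation[acts$pair == "FO"]
  }
  expect_true(all(diff(rev_act) > 0))
  expect_true(all(diff(can_act) < 0))
  # and the reversed-prime match score inherits the monotonicity
  scores <- vapply(sigmas, function(s)
    noisy_ob_match("fo", "OF", policy_seriol(noise_sd = s))$score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("noise calibration matches a grid-search oracle and recovers known sigma", {
  expect_error(calibrate_noise(data.frame()), "at least one")

  published <- data.frame(prime = c("fo", "hte"), target = c("OF", "THE"),
                          score = c(0.27, 0.62))
  fit <- calibrate_noise(published)
  grid <- oracle_sigma_grid(published)
  expect_lt(abs(fit$sigma - grid$sigma), 0.011)  # within grid resolution
  expect_lte(fit$sse, grid$sse + 1e-8)
  expect_length(fit$residuals, 2L)

  # self-consistency: scores generated by the model at a known sigma
  sigma_true <- 0.7
  pairs <- data.frame(prime = c("fo", "hte", "ob", "jugde"),
                      target = c("OF", "THE", "ABOLISH", "JUDGE"))
  pairs$score <- vapply(seq_len(nrow(pairs)), function(k)
    noisy_ob_match(pairs$prime[k], pairs$target[k],
                   policy_seriol(noise_sd = sigma_true))$score, numeric(1))
  refit <- calibrate_noise(pairs)
  expect_equal(refit$sigma, sigma_true, tolerance = 0.01)
})

test_that("slot coding counts aligned positions only", {
  expect_equal(slot_coding_match("jugde", "JUDGE")$score, 3 / 5)
  # transposed and substituted primes are indistinguishable under slot coding
  expect_equal(slot_coding_match("junpe", "JUDGE")$score,
               slot_coding_match("jugde", "JUDGE")$score)
  # anagrams share only the slots where the permutation is fixed: the
  # final T of CAT/ACT stays in place, the other letters do not
  expect_equal(slot_coding_match("CAT", "ACT")$score, 1 / 3)
  expect_equal(slot_coding_match("TRAP", "PART")$score, 0)  # full derangement
  expect_equal(slot_coding_match("pray", "PRAYS")$score, 4 / 5)
})

test_that("gradient match respects the spatial-gradient ordinal predictions", {
  expect_equal(gradient_match("abolish", "ABOLISH")$score, 1)
  expect_equal(gradient_match("we", "ABOLISH")$score, 0)
  expect_gte(gradient_match("bo", "ABOLISH")$score,
             gradient_match("bs", "ABOLISH")$score)
  # reversal leaves the letter set unchanged, so this simplified coder
  # scores reversed bigram primes above zero
  expect_gt(gradient_match("sb", "ABOLISH")$score, 0)
  expect_error(gradient_match("ab", "ABS", decay = 1.2))
})

test_that("all models score in [0,1], identity = 1, letter-disjoint = 0", {
  set.seed(61)
  halves <- list(LETTERS[1:13], LETTERS[14:26])
  for (k in 1:25) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    a <- paste(sample(halves[[1]], n1), collapse = "")
    b <- paste(sample(halves[[2]], n2), collapse = "")
    sc_ab <- score_pair(a, b)
    sc_id <- score_pair(b, b)
    expect_true(all(sc_ab >= 0 & sc_ab <= 1))
    expect_true(all(abs(sc_id - 1) < 1e-12))
    expect_true(all(sc_ab == 0))  # disjoint alphabets share nothing
  }
})
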