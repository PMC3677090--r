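small_design <- function(...) {
  design_spec(n_subjects = 6L, n_items = 10L, seed = 7L, ...)
}

test_that("design validation catches impossible parameters", {
  expect_error(design_spec(conditions = c(TL = 57, ALD = 5)),
               "control condition")
  expect_error(design_spec(conditions = c(TL = 500, ALD = 0),
                           baseline_rt = 477), "nonpositive")
  expect_error(design_spec(n_subjects = 0))
})

test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_experiment(small_design())
  b <- simulate_experiment(small_design())
  expect_identical(a, b)
  c <- simulate_experiment(small_design(), seed = 8L)
  expect_false(identical(a, c))
  # schema and invariants
  expect_named(a, c("subject", "item", "referent", "condition", "response",
                    "rt_ms", "correct"))
  expect_true(all(a$rt_ms > 0))
  expect_true(all(a$correct %in% 0:1))
  expect_true(all(a$referent[a$response == "Same"] == a$item[a$response == "Same"]))
  expect_true(all(a$referent[a$response == "Different"] !=
                    a$item[a$response == "Different"]))
})

test_that("RT cutoff removes exactly the sub-cutoff analysis rows", {
  tr <- simulate_experiment(small_design())
  res <- apply_rt_cutoff(tr)
  expect_equal(res$n_excluded,
               sum(tr$response == "Same" & tr$correct == 1 & tr$rt_ms < 250))
  expect_equal(nrow(res$trials) + res$n_excluded, nrow(tr))

  # handcrafted set: three analysis rows below the cutoff, one protected
  # Different row and one protected error row stay
  hand <- data.frame(subject = "s01", item = "item001", referent = "item001",
                     condition = "TL",
                     response = c("Same", "Same", "Same", "Different", "Same"),
                     rt_ms = c(200, 249, 100, 180, 400),
                     correct = c(1, 1, 1, 1, 0))
  res2 <- apply_rt_cutoff(hand)
  expect_equal(res2$n_excluded, 3L)
  expect_equal(nrow(res2$trials), 2L)

  # heavy-noise simulation: count equals an independent scan
  noisy <- simulate_experiment(small_design(sd_resid = 1.2, baseline_rt = 350))
  res3 <- apply_rt_cutoff(noisy)
  expect_equal(res3$n_excluded,
               sum(noisy$response == "Same" & noisy$correct == 1 &
                     noisy$rt_ms < 250))
  expect_gt(res3$n_excluded, 0)

  none <- hand[hand$rt_ms >= 250, ]
  expect_equal(apply_rt_cutoff(none)$n_excluded, 0L)
})

test_that("a null design recovers effects near zero with covering CIs", {
  des <- design_spec(conditions = c(identity = 0, TL = 0, ALD = 0),
                     error_rates = c(identity = 0.05, TL = 0.05, ALD = 0.05),
                     seed = 17L)
  tr <- apply_rt_cutoff(simulate_experiment(des))$trials
  rec <- recover_effects(tr, n_boot = 1000, seed = 18L)
  expect_true(all(rec$effects$ci_lo <= 0 & rec$effects$ci_hi >= 0))
  expect_true(all(abs(rec$effects$delta_ms) < 30))
  expect_false(rec$unreliable)
})

test_that("injected effects are recovered without bias at experiment scale", {
  # 25 replicates; the mean recovered effect must sit within 2 SEM of the
  # injected 57 ms
  set.seed(23)
  seeds <- sample.int(2^31 - 1, 25)
  deltas <- vapply(seeds, function(s) {
    tr <- apply_rt_cutoff(simulate_experiment(design_spec(seed = s)))$trials
    ana <- tr[tr$response == "Same" & tr$correct == 1, ]
    m <- tapply(ana$rt_ms, ana$condition, mean)
    unname(m["ALD"] - m["TL"])
  }, numeric(1))
  sem <- stats::sd(deltas) / sqrt(length(deltas))
  expect_lt(abs(mean(deltas) - 57), 2 * sem + 1e-9)
})

test_that("Different-trial condition means are equal by construction", {
  des <- design_spec(n_subjects = 24L, n_items = 30L, seed = 29L)
  tr <- simulate_experiment(des)
  diff_tr <- tr[tr$response == "Different" & tr$correct == 1, ]
  fit <- stats::anova(stats::lm(rt_ms ~ condition, data = diff_tr))
  expect_gt(fit[["Pr(>F)"]][1L], 0.001)
  m <- tapply(diff_tr$rt_ms, diff_tr$condition, mean)
  expect_lt(max(m) - min(m), 20)
})

test_that("recover_effects reports degenerate inputs instead of failing silently", {
  tr <- simulate_experiment(small_design())
  # all trials of one condition wrong: an empty analysis cell is reported
  tr2 <- tr
  tr2$correct[tr2$condition == "TL" & tr2$response == "Same"] <- 0L
  rec <- recover_effects(tr2, n_boot = 200, seed = 31L)
  expect_true("TL" %in% rec$missing_cells)
  # single-subject input: means computed, flagged unreliable
  tr3 <- tr[tr$subject == "s01", ]
  rec3 <- recover_effects(tr3, n_boot = 200, seed = 31L)
  expect_true(rec3$unreliable)
  expect_equal(nrow(rec3$effects), 2L)
  # control condition unusable is an error
  tr4 <- tr
  tr4$correct[tr4$condition == "ALD" & tr4$response == "Same"] <- 0L
  expect_error(recover_effects(tr4), "no analyzable trials")
})

test_that("random_lexicon honors constraints and seeds", {
  words <- random_lexicon(100, 7, seed = 37)
  expect_length(words, 100L)
  expect_true(all(nchar(words) == 7L))
  expect_true(all(vapply(words, function(w)
    !any(duplicated(strsplit(w, "")[[1L]])), logical(1))))
  expect_identical(words, random_lexicon(100, 7, seed = 37))
  expect_error(random_lexicon(5, 27), "26 letters")
  reps <- random_lexicon(50, 9, no_repeats = FALSE, seed = 41)
  expect_true(any(vapply(reps, function(w)
    any(duplicated(strsplit(w, "")[[1L]])), logical(1))))
})

test_that("simulate -> cutoff -> recover -> evaluate closes end-to-end", {
  des <- design_spec(seed = 43L)
  tr <- simulate_experiment(des)
  filtered <- apply_rt_cutoff(tr)
  rec <- recover_effects(filtered$trials, n_boot = 500, seed = 44L)
  observed <- data.frame(target_class = "2L",
                         condition = rec$effects$condition,
                         delta_ms = rec$effects$delta_ms,
                         sig = rec$effects$ci_lo > 0)
  stim <- experiment_stimuli("exp1")
  preds <- predict_conditions(stim[stim$target_class == "2L" &
                                     stim$condition != "ALD", ])
  verdict <- evaluate_models(preds, observed)$verdict
  expect_equal(unname(verdict["binary"]), "inconsistent")
  expect_equal(unname(verdict["gradient"]), "consistent")
})
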