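# Trial-level synthetic data for cross-case same-different masked priming.
#
# The generator works on the inverse-RT scale invRT = -1000 / RT(ms), the
# scale on which such data are approximately Gaussian and on which the
# packaged experiments were analyzed. Priming effects are injected on the
# mean-RT scale (ms) and converted to invRT shifts at the control baseline;
# they apply to Same trials only — Different trials are insensitive to
# masked priming, and the generator builds them with equal condition means
# by construction.

#' Design specification for a simulated same-different experiment
#'
#' Defaults describe the two-letter-word arm of the packaged two/three
#' letter experiment: 12 subjects, 20 items, identity/TL/ALD prime
#' conditions with injected Same-trial priming effects of 97 and 57 ms
#' against a 477 ms control baseline, and per-condition error rates matching
#' the published cells. Variance components live on the invRT scale and are
#' free parameters of the generator, not published quantities.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param n_items Number of target items (default 20).
#' @param conditions Named numeric vector of injected Same-trial priming
#'   effects in ms relative to the control; the control itself must be
#'   present with effect 0.
#' @param control Name of the control condition (default `"ALD"`).
#' @param baseline_rt Control-condition Same-trial mean RT in ms (477).
#' @param diff_baseline_rt Different-trial mean RT in ms, common to all
#'   conditions (474).
#' @param error_rates Named per-condition Same-trial error probabilities.
#' @param diff_error_rate Different-trial error probability (all conditions).
#' @param sd_subject,sd_item,sd_resid Subject, item and residual SDs on the
#'   invRT scale (defaults 0.15, 0.05, 0.35; at a 477 ms baseline the
#'   residual corresponds to roughly an 80 ms trial-level RT spread).
#' @param reps Repetitions of each (item, condition, response) cell per
#'   subject (default 1).
#' @param max_rt Response deadline in ms; simulated RTs are censored at
#'   this value (default 2000).
#' @param seed Integer seed stored with the design; [simulate_experiment()]
#'   uses it unless overridden.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_subjects = 12L, n_items = 20L,
                        conditions = c(identity = 97, TL = 57, ALD = 0),
                        control = "ALD",
                        baseline_rt = 477, diff_baseline_rt = 474,
                        error_rates = c(identity = 0.021, TL = 0.075,
                                        ALD = 0.092),
                        diff_error_rate = 0.05,
                        sd_subject = 0.15, sd_item = 0.05, sd_resid = 0.35,
                        reps = 1L, max_rt = 2000, seed = 1L) {
  stopifnot(n_subjects >= 1L, n_items >= 1L, reps >= 1L,
            !is.null(names(conditions)), control %in% names(conditions),
            sd_subject >= 0, sd_item >= 0, sd_resid >= 0,
            baseline_rt > 0, diff_baseline_rt > 0, max_rt > 0)
  if (conditions[[control]] != 0) {
    stop("the control condition must have an injected effect of 0")
  }
  if (any(baseline_rt - conditions <= 0)) {
    stop("injected effects imply a nonpositive condition mean RT")
  }
  er <- rep(0.05, length(conditions))
  names(er) <- names(conditions)
  er[names(error_rates)[names(error_rates) %in% names(conditions)]] <-
    error_rates[names(error_rates) %in% names(conditions)]
  stopifnot(all(er >= 0), all(er <= 1),
            diff_error_rate >= 0, diff_error_rate <= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), n_items = as.integer(n_items),
         conditions = conditions, control = control,
         baseline_rt = baseline_rt, diff_baseline_rt = diff_baseline_rt,
         error_rates = er, diff_error_rate = diff_error_rate,
         sd_subject = sd_subject, sd_item = sd_item, sd_resid = sd_resid,
         reps = as.integer(reps), max_rt = max_rt, seed = as.integer(seed)),
    class = "design_spec"
  )
}

# Expected mean RT (ms) when invRT ~ N(mu, sd), censored at the deadline.
# Because RT = -1000/invRT is convex in invRT, the mean RT exceeds
# -1000/mu; condition shifts must be derived through this expectation or
# the injected ms effects would be biased upward.
expected_rt <- function(mu, sd, max_rt) {
  cap <- -1000 / max_rt
  if (sd == 0) return(min(-1000 / mu, max_rt))
  upper <- min(cap, mu + 12 * sd)
  val <- stats::integrate(function(x) (-1000 / x) * stats::dnorm(x, mu, sd),
                          lower = mu - 12 * sd, upper = upper,
                          rel.tol = 1e-10)$value
  val + max_rt * stats::pnorm(cap, mu, sd, lower.tail = FALSE)
}

# invRT location whose censored-normal mean RT equals `target_rt`.
invrt_mu_for_mean_rt <- function(target_rt, sd, max_rt, start) {
  stats::uniroot(function(m) expected_rt(m, sd, max_rt) - target_rt,
                 interval = c(start - 5, -1000 / max_rt - 1e-8),
                 tol = 1e-10)$root
}

#' Simulate trial-level same-different RT data
#'
#' Generates one trial per (subject, item, condition, response, repetition)
#' cell. On the invRT scale, a trial is baseline + subject effect + item
#' effect + condition shift + Gaussian residual. The condition shift
#' (applied to Same trials only; Different-trial condition means are equal
#' by construction) is derived so that the *expected mean RT* of the
#' condition sits exactly `delta` ms below the control's expected mean RT,
#' accounting for the convexity of the invRT-to-RT transform — a
#' first-order shift at the baseline would inflate the realized effects.
#' Accuracy is independent Bernoulli per condition. RTs are censored at the
#' response deadline; no lower cutoff is applied here — filtering is a
#' separate step ([apply_rt_cutoff()]).
#'
#' @param design A [design_spec()].
#' @param seed Integer seed; defaults to `design$seed`.
#' @return Data frame of trials: `subject`, `item`, `referent`, `condition`,
#'   `response`, `rt_ms`, `correct`.
#' @examples
#' trials <- simulate_experiment(design_spec(n_subjects = 4, n_items = 6))
#' head(trials)
#' @export
simulate_experiment <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "design_spec"))
  set.seed(seed)
  S <- design$n_subjects; I <- design$n_items
  conds <- names(design$conditions)
  grid <- expand.grid(rep = seq_len(design$reps),
                      response = c("Same", "Different"),
                      condition = conds,
                      item = seq_len(I), subject = seq_len(S),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(grid)
  subj_eff <- stats::rnorm(S, 0, design$sd_subject)
  item_eff <- stats::rnorm(I, 0, design$sd_item)
  sd_tot <- sqrt(design$sd_subject^2 + design$sd_item^2 + design$sd_resid^2)
  mu0 <- -1000 / design$baseline_rt
  rt0 <- expected_rt(mu0, sd_tot, design$max_rt)
  mu_same <- vapply(design$conditions, function(delta) {
    if (delta == 0) mu0
    else invrt_mu_for_mean_rt(rt0 - delta, sd_tot, design$max_rt, mu0)
  }, numeric(1))
  mu_diff <- -1000 / design$diff_baseline_rt
  is_same <- grid$response == "Same"
  mu <- ifelse(is_same, mu_same[grid$condition], mu_diff)
  invrt <- mu + subj_eff[grid$subject] + item_eff[grid$item] +
    stats::rnorm(n, 0, design$sd_resid)
  # censor at the response deadline (invRT is negative; larger = slower)
  invrt <- pmin(invrt, -1000 / design$max_rt)
  rt <- -1000 / invrt
  p_err <- ifelse(is_same, design$error_rates[grid$condition],
                  design$diff_error_rate)
  correct <- as.integer(stats::runif(n) >= p_err)
  item_id <- sprintf("item%03d", grid$item)
  referent <- ifelse(is_same, item_id,
                     sprintf("item%03d", (grid$item %% I) + 1L))
  out <- data.frame(subject = sprintf("s%02d", grid$subject),
                    item = item_id, referent = referent,
                    condition = grid$condition, response = grid$response,
                    rt_ms = rt, correct = correct,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Apply the short-RT exclusion cutoff
#'
#' Removes, from the analysis set (correct Same trials), rows with RT below
#' the cutoff (default 250 ms), and reports how many were removed. Other
#' rows are untouched; raw generation and filtering are deliberately
#' separate steps.
#'
#' @param trials Trial data frame as produced by [simulate_experiment()].
#' @param cutoff_ms Lower RT cutoff in ms, default 250.
#' @return List with `trials` (filtered data frame) and `n_excluded`.
#' @export
apply_rt_cutoff <- function(trials, cutoff_ms = 250) {
  stopifnot(all(c("response", "correct", "rt_ms") %in% names(trials)))
  analysis <- trials$response == "Same" & trials$correct == 1L
  drop <- analysis & trials$rt_ms < cutoff_ms
  list(trials = trials[!drop, , drop = FALSE],
       n_excluded = sum(drop))
}

#' Condition means and bootstrap priming-effect estimates
#'
#' Computes per-condition mean RTs over correct Same trials, priming
#' effects relative to the control condition, and percentile bootstrap
#' confidence intervals obtained by resampling subjects (the clustering
#' unit) with replacement.
#'
#' @param trials Trial data frame (typically after [apply_rt_cutoff()]).
#' @param control Control condition label, default `"ALD"`.
#' @param n_boot Bootstrap resamples, default 2000.
#' @param conf Confidence level, default 0.95.
#' @param seed Optional integer seed for the bootstrap.
#' @return List with `cell_means` (condition, response, mean RT, n),
#'   `effects` (condition, `delta_ms`, `ci_lo`, `ci_hi`), `missing_cells`
#'   (character vector, empty when the design is complete), `n_boot`,
#'   `conf`, and `unreliable` (`TRUE` with fewer than 2 subjects).
#' @export
recover_effects <- function(trials, control = "ALD", n_boot = 2000L,
                            conf = 0.95, seed = NULL) {
  stopifnot(all(c("subject", "condition", "response", "rt_ms", "correct")
                %in% names(trials)))
  if (!is.null(seed)) set.seed(seed)
  cell_means <- stats::aggregate(rt_ms ~ condition + response,
                                 data = trials[trials$correct == 1L, ],
                                 FUN = mean)
  cell_means$n <- stats::aggregate(rt_ms ~ condition + response,
                                   data = trials[trials$correct == 1L, ],
                                   FUN = length)$rt_ms
  names(cell_means)[names(cell_means) == "rt_ms"] <- "mean_rt"

  ana <- trials[trials$response == "Same" & trials$correct == 1L, , drop = FALSE]
  if (nrow(ana) == 0L) stop("no correct Same trials to analyze")
  conds <- sort(unique(trials$condition[trials$response == "Same"]))
  if (!control %in% conds) stop(sprintf("control condition '%s' absent", control))
  if (length(conds) < 2L) stop("need at least two conditions including the control")
  subjects <- sort(unique(ana$subject))
  S <- length(subjects)
  sums <- matrix(0, S, length(conds), dimnames = list(subjects, conds))
  cnts <- matrix(0, S, length(conds), dimnames = list(subjects, conds))
  agg_s <- tapply(ana$rt_ms, list(ana$subject, ana$condition), sum)
  agg_n <- tapply(ana$rt_ms, list(ana$subject, ana$condition), length)
  sums[rownames(agg_s), colnames(agg_s)] <- ifelse(is.na(agg_s), 0, agg_s)
  cnts[rownames(agg_n), colnames(agg_n)] <- ifelse(is.na(agg_n), 0, agg_n)
  missing_cells <- character(0)
  empty <- which(colSums(cnts) == 0)
  if (length(empty) > 0L) {
    missing_cells <- conds[empty]
    if (control %in% missing_cells) {
      stop(sprintf("control condition '%s' has no analyzable trials", control))
    }
  }
  point_means <- colSums(sums) / colSums(cnts)
  noncontrol <- setdiff(conds, control)
  delta <- point_means[control] - point_means[noncontrol]

  boot <- matrix(NA_real_, n_boot, length(noncontrol),
                 dimnames = list(NULL, noncontrol))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(S, S, replace = TRUE)
    m <- colSums(sums[idx, , drop = FALSE]) / colSums(cnts[idx, , drop = FALSE])
    boot[b, ] <- m[control] - m[noncontrol]
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boot, 2L, stats::quantile,
              probs = c(alpha, 1 - alpha), na.rm = TRUE)
  effects <- data.frame(condition = noncontrol,
                        delta_ms = unname(delta),
                        ci_lo = ci[1L, ], ci_hi = ci[2L, ],
                        stringsAsFactors = FALSE)
  rownames(effects) <- NULL
  list(cell_means = cell_means, effects = effects,
       missing_cells = missing_cells, n_boot = n_boot, conf = conf,
       unreliable = S < 2L)
}

#' Random word list for property tests
#'
#' Uniformly samples letter strings of a given length, optionally with no
#' repeated letters, reproducibly under a seed.
#'
#' @param n Number of words.
#' @param length Word length; at most 26 when `no_repeats`.
#' @param no_repeats Forbid repeated letters within a word? Default `TRUE`.
#' @param seed Optional integer seed.
#' @return Character vector of `n` uppercase words.
#' @examples
#' random_lexicon(5, 7, seed = 42)
#' @export
random_lexicon <- function(n, length, no_repeats = TRUE, seed = NULL) {
  stopifnot(n >= 1L, length >= 1L)
  if (no_repeats && length > 26L) {
    stop("cannot build strings longer than 26 letters without repeats")
  }
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(k) {
    l <- sample(LETTERS, length, replace = !no_repeats)
    paste(l, collapse = "")
  }, character(1))
}
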