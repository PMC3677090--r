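# Condition-level priming tables, model prediction tables, and the
# zero-overlap falsification comparison.
#
# The logic of the comparison: if a coding scheme assigns a prime-target
# pair a match score of exactly 0, the prime's code carries no information
# about the target under that scheme, so nothing downstream of the code
# could produce priming. A condition with score 0 but a positive, reliable
# observed priming effect therefore falsifies the scheme, independently of
# its downstream parameters.

.pipeline_env <- new.env(parent = emptyenv())

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "orthoprime")
  if (p == "") p <- file.path("inst", "extdata", file)  # pre-install fallback
  if (!file.exists(p)) stop(sprintf("fixture '%s' not found", file))
  p
}

#' Representative stimuli for each packaged experiment
#'
#' Returns the prime-target pairs used to generate model predictions: the
#' worked examples of each design (OF/THE families for the two- and
#' three-letter experiment, the ABOLISH family for the seven-letter bigram
#' experiments).
#'
#' @param experiment One of `"exp1"`, `"exp2"`, `"exp3"`.
#' @return Data frame with columns `target_class`, `condition`, `prime`,
#'   `target`.
#' @export
experiment_stimuli <- function(experiment = c("exp1", "exp2", "exp3")) {
  experiment <- match.arg(experiment)
  switch(experiment,
    exp1 = data.frame(
      target_class = rep(c("2L", "3L"), each = 3L),
      condition = rep(c("identity", "TL", "ALD"), 2L),
      prime = c("of", "fo", "ym", "the", "hte", "nma"),
      target = rep(c("OF", "THE"), each = 3L),
      stringsAsFactors = FALSE),
    exp2 = data.frame(
      target_class = "7L",
      condition = c("0L", "1L", "3L", "ALD"),
      prime = c("bo", "bl", "bs", "du"),
      target = "ABOLISH", stringsAsFactors = FALSE),
    exp3 = data.frame(
      target_class = "7L",
      condition = c("0L", "3L", "rev0L", "rev3L", "ALD"),
      prime = c("bo", "bs", "ob", "sb", "du"),
      target = "ABOLISH", stringsAsFactors = FALSE))
}

#' Load a packaged condition-level priming table
#'
#' Reads the transcribed mean response latencies (ms) and percent error
#' rates for one of the three packaged masked-priming same-different
#' experiments, and validates the schema: positive RTs, error rates in
#' `[0,100]`, and an all-letters-different (ALD) control cell for every
#' Same-response target class. `sig_flag` records whether the condition's
#' Same-trial priming effect was reported reliable.
#'
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @param path Optional path to an alternative CSV with the same columns.
#' @return A `priming_table`: a data frame with columns `experiment`,
#'   `response`, `target_class`, `condition`, `prime_example`, `rt_ms`,
#'   `pct_error`, `sig_flag`, and attributes `experiment` and `control`.
#' @examples
#' tab <- load_priming_table("exp1")
#' subset(tab, response == "Same" & condition == "ALD")$rt_ms  # 477 471
#' @export
load_priming_table <- function(experiment = c("exp1", "exp2", "exp3"),
                               path = NULL) {
  experiment <- match.arg(experiment)
  src <- if (is.null(path)) extdata_path("priming_tables.csv") else path
  all_tab <- utils::read.csv(src, stringsAsFactors = FALSE)
  need <- c("experiment", "response", "target_class", "condition",
            "prime_example", "rt_ms", "pct_error", "sig_flag")
  missing_cols <- setdiff(need, names(all_tab))
  if (length(missing_cols) > 0L) {
    stop(sprintf("malformed priming table: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- all_tab[all_tab$experiment == experiment, need, drop = FALSE]
  if (nrow(tab) == 0L) stop(sprintf("no rows for experiment '%s'", experiment))
  if (any(!is.finite(tab$rt_ms)) || any(tab$rt_ms <= 0)) {
    stop("malformed priming table: RTs must be positive")
  }
  if (any(tab$pct_error < 0 | tab$pct_error > 100)) {
    stop("malformed priming table: error rates must lie in [0,100]")
  }
  same <- tab[tab$response == "Same", , drop = FALSE]
  for (cls in unique(same$target_class)) {
    if (!"ALD" %in% same$condition[same$target_class == cls]) {
      stop(sprintf("no ALD control cell for Same-response class '%s'", cls))
    }
  }
  rownames(tab) <- NULL
  structure(tab, experiment = experiment, control = "ALD",
            class = c("priming_table", "data.frame"))
}

#' Priming effects from a condition-level table
#'
#' For every Same-response non-control condition, the priming effect is the
#' control (ALD) mean RT minus the condition mean RT, in ms, within target
#' class. Only Same trials enter: in the cross-case same-different task the
#' Different trials show no masked priming, and the packaged tables reflect
#' that.
#'
#' @param table A `priming_table` (from [load_priming_table()]) or a data
#'   frame with the same columns.
#' @param control Control condition label, default `"ALD"`.
#' @return Data frame with columns `target_class`, `condition`, `delta_ms`
#'   (control RT minus condition RT), `delta_pct_error`, and `sig`.
#' @examples
#' compute_priming_effects(load_priming_table("exp1"))
#' @export
compute_priming_effects <- function(table, control = "ALD") {
  tab <- as.data.frame(table)
  same <- tab[tab$response == "Same", , drop = FALSE]
  if (nrow(same) == 0L) stop("no Same-response cells present")
  out <- lapply(unique(same$target_class), function(cls) {
    sub <- same[same$target_class == cls, , drop = FALSE]
    ctrl <- sub[sub$condition == control, , drop = FALSE]
    if (nrow(ctrl) != 1L) {
      stop(sprintf("missing or duplicated %s control cell in class '%s'",
                   control, cls))
    }
    cond <- sub[sub$condition != control, , drop = FALSE]
    data.frame(target_class = cls, condition = cond$condition,
               delta_ms = ctrl$rt_ms - cond$rt_ms,
               delta_pct_error = ctrl$pct_error - cond$pct_error,
               sig = as.logical(cond$sig_flag),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Model match scores for a set of prime-target conditions
#'
#' Scores each (prime, target) row of a stimulus table under each requested
#' model, producing the long-format prediction table consumed by
#' [evaluate_models()].
#'
#' @param stimuli Data frame with columns `condition`, `prime`, `target`
#'   and optionally `target_class` (inferred from target length otherwise).
#' @param models Character vector of model names (see [score_pair()]).
#' @param policies Named list of per-model [coding_policy()] overrides.
#' @param decay Decay parameter of the gradient model.
#' @return A `prediction_table` data frame: `model`, `target_class`,
#'   `condition`, `prime`, `target`, `score`.
#' @export
predict_conditions <- function(stimuli,
                               models = c("binary", "weighted", "noisy",
                                          "slot", "gradient"),
                               policies = list(), decay = 0.7) {
  stopifnot(all(c("condition", "prime", "target") %in% names(stimuli)))
  if (!"target_class" %in% names(stimuli)) {
    stimuli$target_class <- paste0(nchar(stimuli$target), "L")
  }
  rows <- lapply(seq_len(nrow(stimuli)), function(k) {
    sc <- score_pair(stimuli$prime[k], stimuli$target[k], models,
                     policies, decay)
    data.frame(model = names(sc),
               target_class = stimuli$target_class[k],
               condition = stimuli$condition[k],
               prime = stimuli$prime[k], target = stimuli$target[k],
               score = unname(sc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("prediction_table", "data.frame"))
}

#' Prediction table for a packaged experiment
#'
#' @inheritParams predict_conditions
#' @param experiment `"exp1"`, `"exp2"` or `"exp3"`.
#' @return A `prediction_table` over that experiment's representative
#'   stimuli.
#' @examples
#' predict_experiment("exp2", models = c("binary", "weighted"))
#' @export
predict_experiment <- function(experiment,
                               models = c("binary", "weighted", "noisy",
                                          "slot", "gradient"),
                               policies = list(), decay = 0.7) {
  predict_conditions(experiment_stimuli(experiment), models, policies, decay)
}

#' Zero-overlap falsification check of model predictions
#'
#' Flags every (model, condition) pair whose predicted match score is
#' exactly 0 while the observed priming effect is positive (and, by
#' default, reported reliable). A model with any flagged condition is
#' declared inconsistent with the data: a zero match score means the
#' model's orthographic code retains nothing of the target, so no
#' downstream mechanism could generate the observed priming.
#'
#' @param predictions A `prediction_table` (from [predict_conditions()] or
#'   [predict_experiment()]).
#' @param observed A `priming_table`, or a data frame of effects with
#'   columns `target_class`, `condition`, `delta_ms`, `sig` (as returned by
#'   [compute_priming_effects()]).
#' @param delta_threshold Priming effects must exceed this (ms) to count as
#'   positive; default 0.
#' @param require_sig Require the stored reliability flag as well? Default
#'   `TRUE`.
#' @param tol Scores `<= tol` count as exactly zero; default `1e-12`.
#' @param control Control condition label; prediction rows for it are not
#'   compared (it has no priming effect by definition). Default `"ALD"`.
#' @return A `falsification_report`: list with `flags` (data frame of
#'   flagged rows) and `verdict` (named character vector per model,
#'   `"inconsistent"` or `"consistent"`).
#' @examples
#' preds <- predict_experiment("exp1", models = "binary")
#' evaluate_models(preds, load_priming_table("exp1"))$verdict
#' @export
evaluate_models <- function(predictions, observed, delta_threshold = 0,
                            require_sig = TRUE, tol = 1e-12,
                            control = "ALD") {
  stopifnot(inherits(predictions, "data.frame"))
  effects <- if (inherits(observed, "priming_table")) {
    compute_priming_effects(observed)
  } else {
    obs <- as.data.frame(observed)
    stopifnot(all(c("condition", "delta_ms") %in% names(obs)))
    if (!"target_class" %in% names(obs)) {
      obs$target_class <- unique(predictions$target_class)[1L]
    }
    if (!"sig" %in% names(obs)) obs$sig <- TRUE
    obs
  }
  preds <- as.data.frame(predictions)
  preds <- preds[preds$condition != control, , drop = FALSE]
  merged <- merge(preds, effects, by = c("target_class", "condition"))
  if (nrow(merged) == 0L) {
    stop("no overlapping (target_class, condition) cells between predictions and observations")
  }
  unmatched <- setdiff(paste(preds$target_class, preds$condition),
                       paste(merged$target_class, merged$condition))
  if (length(unmatched) > 0L) {
    stop(sprintf("prediction condition(s) missing from observations: %s",
                 paste(unmatched, collapse = "; ")))
  }
  pos <- merged$delta_ms > delta_threshold
  if (require_sig) pos <- pos & !is.na(merged$sig) & merged$sig
  flagged <- merged[merged$score <= tol & pos, , drop = FALSE]
  flagged <- flagged[order(flagged$model, flagged$target_class,
                           flagged$condition), , drop = FALSE]
  rownames(flagged) <- NULL
  verdict <- vapply(sort(unique(merged$model)), function(m) {
    if (m %in% flagged$model) "inconsistent" else "consistent"
  }, character(1))
  structure(list(flags = flagged, verdict = verdict),
            class = "falsification_report")
}

#' @export
print.falsification_report <- function(x, ...) {
  cat("<falsification_report>\n")
  for (m in names(x$verdict)) {
    cat(sprintf("  %-12s %s\n", m, x$verdict[[m]]))
  }
  if (nrow(x$flags) > 0L) {
    cat("  flagged conditions (score = 0, observed priming > 0):\n")
    print.data.frame(x$flags[, c("model", "target_class", "condition",
                                 "prime", "target", "score", "delta_ms")],
                     row.names = FALSE)
  }
  invisible(x)
}

#' Recompute the packaged printed quantities and compare
#'
#' Recomputes, from the package's own operations and fixtures, each
#' reference quantity shipped with the package (bigram counts, the
#' degenerate repeated-letter match score, and every condition-level
#' priming effect of the three experiments) and compares it with the stored
#' printed value.
#'
#' @param experiments Experiments whose priming effects to include.
#' @return Data frame with columns `quantity`, `computed`, `printed`,
#'   `match`; attribute `all_match` is `TRUE` when every row agrees.
#' @export
reproduce_report <- function(experiments = c("exp1", "exp2", "exp3")) {
  printed <- utils::read.csv(extdata_path("printed_values.csv"),
                             stringsAsFactors = FALSE)
  computed <- c(
    judge_unconstrained_ob_count =
      nrow(extract_open_bigrams("JUDGE", policy_unbounded())),
    jugde_judge_shared_obs =
      length(binary_ob_match("jugde", "JUDGE", policy_unbounded())$shared),
    junpe_judge_shared_obs =
      length(binary_ob_match("junpe", "JUDGE", policy_unbounded())$shared),
    span2_ob_count_7letter =
      count_open_bigrams(7, coding_policy(max_gap = 2)),
    casaca_casa_binary_match =
      binary_ob_match("casaca", "CASA", coding_policy(max_gap = 2))$score
  )
  for (exp in experiments) {
    eff <- compute_priming_effects(load_priming_table(exp))
    vals <- stats::setNames(
      eff$delta_ms,
      sprintf("%s_%s_%s_priming_ms", exp, eff$target_class, eff$condition))
    computed <- c(computed, vals)
  }
  keep <- printed$quantity %in% names(computed)
  printed <- printed[keep, , drop = FALSE]
  out <- data.frame(quantity = printed$quantity,
                    computed = unname(computed[printed$quantity]),
                    printed = printed$printed,
                    stringsAsFactors = FALSE)
  out$match <- abs(out$computed - out$printed) < 1e-9
  attr(out, "all_match") <- all(out$match)
  out
}
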