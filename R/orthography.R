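# Core letter-string and open-bigram machinery.
#
# An open bigram is an ordered pair of letters from a word, contiguous or
# separated by intervening letters. A word is coded as an unordered set of
# such pairs; which pairs enter the code, and with what weight, is governed
# by a coding policy (gap limit, edge markers, per-gap weights, positional
# noise).

#' Normalize raw text into a letter string
#'
#' Upper-cases the input, strips surrounding whitespace, and validates that
#' only letters A-Z remain. Positions are 1-based. The returned object also
#' records whether any letter occurs more than once, because closed-form
#' bigram counts (and several stimulus constraints) assume no repeated
#' letters.
#'
#' @param text A length-1 character vector.
#' @return An object of class `letter_string` with fields `text` (uppercase
#'   string), `letters` (character vector of single letters), `n` (length),
#'   `has_repeats` (logical) and `repeated_letters` (character vector,
#'   possibly empty).
#' @examples
#' normalize_string("jugde")
#' normalize_string("CASA")$has_repeats
#' @export
normalize_string <- function(text) {
  if (inherits(text, "letter_string")) return(text)
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  txt <- toupper(trimws(text))
  if (nchar(txt) == 0L) stop("empty string after stripping whitespace")
  letters_vec <- strsplit(txt, "", fixed = TRUE)[[1L]]
  bad <- which(!letters_vec %in% LETTERS)
  if (length(bad) > 0L) {
    stop(sprintf("non-alphabetic character '%s' at position %d",
                 letters_vec[bad[1L]], bad[1L]))
  }
  counts <- table(letters_vec)
  reps <- names(counts)[counts > 1L]
  structure(
    list(text = txt, letters = letters_vec, n = length(letters_vec),
         has_repeats = length(reps) > 0L, repeated_letters = reps),
    class = "letter_string"
  )
}

#' @export
print.letter_string <- function(x, ...) {
  cat(sprintf("<letter_string> %s (n = %d%s)\n", x$text, x$n,
              if (x$has_repeats)
                paste0(", repeats: ", paste(x$repeated_letters, collapse = ","))
              else ""))
  invisible(x)
}

as_letter_string <- function(x) {
  if (inherits(x, "letter_string")) x else normalize_string(x)
}

#' Coding policy for open-bigram extraction
#'
#' Bundles the parameters that distinguish the members of the open-bigram
#' model family:
#' \itemize{
#'   \item `max_gap`: the maximum number of intervening letters allowed
#'     between the two members of a pair. The standard local-context
#'     constraint is 2 (a pair spanning three or more letters is not coded);
#'     `Inf` gives the unconstrained code.
#'   \item `include_edges`: whether boundary bigrams (`#C`, `A#`) pairing the
#'     first/last letter with the word-boundary marker `#` are coded. Off by
#'     default; when on, edge bigrams carry weight 1.
#'   \item `gap_weights`: numeric vector of weights in `[0,1]`, element `k`
#'     being the weight of a pair with `k - 1` intervening letters. `NULL`
#'     means binary coding (weight 1 for every admissible gap). Weights for
#'     gaps beyond `max_gap` are forced to 0.
#'   \item `noise_sd`: standard deviation (in letter-position units) of
#'     Gaussian positional noise used by the noisy-position match;
#'     0 means noiseless.
#' }
#'
#' @param max_gap Maximum intervening letters (default 2); may be `Inf`.
#' @param include_edges Include boundary bigrams? Default `FALSE`.
#' @param gap_weights Numeric weights per gap, or `NULL` for binary.
#' @param noise_sd Positional noise SD, default 0.
#' @return An object of class `coding_policy`.
#' @examples
#' coding_policy(max_gap = Inf)          # unconstrained binary code
#' policy_seriol()                       # distance-weighted 1.0 / 0.8 / 0.4
#' @export
coding_policy <- function(max_gap = 2, include_edges = FALSE,
                          gap_weights = NULL, noise_sd = 0) {
  stopifnot(length(max_gap) == 1L, max_gap >= 0,
            is.logical(include_edges), length(include_edges) == 1L,
            length(noise_sd) == 1L, noise_sd >= 0)
  if (!is.null(gap_weights)) {
    stopifnot(is.numeric(gap_weights), all(gap_weights >= 0),
              all(gap_weights <= 1))
    if (is.finite(max_gap) && length(gap_weights) > max_gap + 1) {
      gap_weights[seq.int(max_gap + 2, length(gap_weights))] <- 0
    }
  }
  structure(
    list(max_gap = max_gap, include_edges = include_edges,
         gap_weights = gap_weights, noise_sd = noise_sd),
    class = "coding_policy"
  )
}

#' @export
print.coding_policy <- function(x, ...) {
  gw <- if (is.null(x$gap_weights)) "binary"
        else paste(format(x$gap_weights), collapse = "/")
  cat(sprintf("<coding_policy> max_gap = %s, edges = %s, weights = %s, sigma = %g\n",
              format(x$max_gap), x$include_edges, gw, x$noise_sd))
  invisible(x)
}

#' Unconstrained binary open-bigram policy
#' @return A `coding_policy` with no gap limit and no edge markers.
#' @export
policy_unbounded <- function() coding_policy(max_gap = Inf)

#' Distance-weighted open-bigram policy
#'
#' Adjacent pairs weigh 1.0, pairs spanning one intervening letter 0.8, two
#' intervening letters 0.4, and three or more 0 — the constituent letters are
#' taken to be too far apart to activate the pair.
#'
#' @param include_edges Include boundary bigrams? Default `FALSE`.
#' @param noise_sd Positional noise SD carried by the policy, default 0.
#' @return A `coding_policy`.
#' @export
policy_seriol <- function(include_edges = FALSE, noise_sd = 0) {
  coding_policy(max_gap = 2, include_edges = include_edges,
                gap_weights = c(1.0, 0.8, 0.4), noise_sd = noise_sd)
}

# Weight of a pair with `gap` intervening letters under `policy` (vectorized).
weight_for_gap <- function(policy, gap) {
  w <- numeric(length(gap))
  ok <- gap <= policy$max_gap
  if (is.null(policy$gap_weights)) {
    w[ok] <- 1
  } else {
    idx <- gap + 1L
    has <- ok & idx <= length(policy$gap_weights)
    w[has] <- policy$gap_weights[idx[has]]
  }
  w
}

#' Extract the open-bigram code of a letter string
#'
#' Enumerates every ordered pair of positions `i < j` with at most
#' `policy$max_gap` intervening letters, assigns each the weight of its gap,
#' and collapses repeated letter pairs to a single entry. Pair identity is
#' the letter pair only — gap and edge status are provenance, not identity —
#' so a pair occurring at several gaps keeps the weight of its most
#' favourable (closest) occurrence. Zero-weight entries are dropped. With
#' `include_edges = TRUE`, boundary bigrams `#X` and `X#` are added with
#' weight 1.
#'
#' @param s A `letter_string` or character scalar.
#' @param policy A [coding_policy()].
#' @return An object of class `bigram_code`: a data frame with columns
#'   `pair`, `first`, `second`, `gap`, `edge`, `weight`, plus attributes
#'   `source` (the `letter_string`) and `policy`.
#' @examples
#' extract_open_bigrams("CAT", policy_unbounded())
#' extract_open_bigrams("CASA", coding_policy(max_gap = 2, include_edges = TRUE))
#' @export
extract_open_bigrams <- function(s, policy = coding_policy()) {
  s <- as_letter_string(s)
  stopifnot(inherits(policy, "coding_policy"))
  n <- s$n
  first <- character(0); second <- character(0)
  gap <- integer(0); edge <- logical(0); weight <- numeric(0)
  if (n >= 2L) {
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)  # i < j
    g <- ij[, 2L] - ij[, 1L] - 1L
    keep <- g <= policy$max_gap
    ij <- ij[keep, , drop = FALSE]; g <- g[keep]
    w <- weight_for_gap(policy, g)
    keep <- w > 0
    first <- s$letters[ij[keep, 1L]]
    second <- s$letters[ij[keep, 2L]]
    gap <- as.integer(g[keep]); weight <- w[keep]
    edge <- rep(FALSE, sum(keep))
  }
  df <- data.frame(pair = paste0(first, second), first = first,
                   second = second, gap = gap, edge = edge, weight = weight,
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0L) {
    # collapse repeated pairs: max weight wins; closest gap as provenance
    ord <- order(df$pair, -df$weight, df$gap)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$pair), , drop = FALSE]
  }
  if (policy$include_edges) {
    edges <- data.frame(
      pair = c(paste0("#", s$letters[1L]), paste0(s$letters[n], "#")),
      first = c("#", s$letters[n]), second = c(s$letters[1L], "#"),
      gap = NA_integer_, edge = TRUE, weight = 1,
      stringsAsFactors = FALSE)
    edges <- edges[!duplicated(edges$pair), , drop = FALSE]
    df <- rbind(df, edges)
  }
  rownames(df) <- NULL
  structure(df, source = s, policy = policy,
            class = c("bigram_code", "data.frame"))
}

#' @export
print.bigram_code <- function(x, ...) {
  src <- attr(x, "source")
  cat(sprintf("<bigram_code> %s: %d entries\n", src$text, nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Closed-form open-bigram count for a no-repeat string
#'
#' For a string of length `n` with no repeated letters, the number of coded
#' pairs is the sum over pair distances `d = 1 .. min(max_gap + 1, n - 1)` of
#' `n - d` (counting only gaps whose weight is nonzero), plus 2 boundary
#' bigrams when edges are enabled. A 7-letter word under the gap-2
#' constraint has 15 internal pairs; a 5-letter word under the unconstrained
#' policy has 10.
#'
#' @param n String length, `>= 1`.
#' @param policy A [coding_policy()].
#' @return Integer count. Valid only under the no-repeat assumption.
#' @examples
#' count_open_bigrams(7, coding_policy(max_gap = 2))  # 15
#' count_open_bigrams(5, policy_unbounded())          # 10
#' @export
count_open_bigrams <- function(n, policy = coding_policy()) {
  stopifnot(length(n) == 1L, n >= 1)
  n <- as.integer(n)
  dmax <- min(policy$max_gap + 1, n - 1)
  total <- 0L
  if (dmax >= 1) {
    d <- seq_len(dmax)
    w <- weight_for_gap(policy, d - 1L)
    total <- sum((n - d)[w > 0])
  }
  as.integer(total + if (policy$include_edges) 2L else 0L)
}
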