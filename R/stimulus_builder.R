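# Construction of masked-priming primes from target words.
#
# Convention: primes are emitted in lowercase and targets in uppercase,
# mirroring the cross-case same-different task (referent and prime in
# lowercase, target in uppercase).

#' Transposed-letter (TL) prime
#'
#' Swaps the letters at positions `i` and `i + 1` of the word and returns
#' the result in lowercase. Applying the same transposition twice restores
#' the word.
#'
#' @param word A letter string or character scalar.
#' @param i 1-based position of the first of the two adjacent letters,
#'   `1 <= i < n`.
#' @return Lowercase prime string.
#' @examples
#' make_tl_prime("OF", 1)     # "fo"
#' make_tl_prime("JUDGE", 3)  # "jugde"
#' @export
make_tl_prime <- function(word, i) {
  w <- as_letter_string(word)
  stopifnot(length(i) == 1L)
  if (i < 1 || i >= w$n) {
    stop(sprintf("transposition position %d out of range for a %d-letter word",
                 i, w$n))
  }
  l <- w$letters
  l[c(i, i + 1L)] <- l[c(i + 1L, i)]
  tolower(paste(l, collapse = ""))
}

#' Substituted-letter (SL) prime
#'
#' Replaces the letters at the given positions with replacement letters that
#' must not occur anywhere in the word (otherwise the substitution would
#' create spurious letter overlap).
#'
#' @param word A letter string or character scalar.
#' @param positions Integer vector of 1-based positions to replace.
#' @param replacements Character vector of single letters, same length as
#'   `positions`, none present in `word`.
#' @return Lowercase prime string.
#' @examples
#' make_sl_prime("JUDGE", c(3, 4), c("N", "P"))  # "junpe"
#' @export
make_sl_prime <- function(word, positions, replacements) {
  w <- as_letter_string(word)
  repl <- toupper(replacements)
  stopifnot(length(positions) == length(repl), all(nchar(repl) == 1L))
  if (any(positions < 1 | positions > w$n)) stop("substitution position out of range")
  clash <- repl[repl %in% w$letters]
  if (length(clash) > 0L) {
    stop(sprintf("replacement letter(s) %s already occur in %s",
                 paste(clash, collapse = ", "), w$text))
  }
  l <- w$letters
  l[positions] <- repl
  tolower(paste(l, collapse = ""))
}

#' Specification of a two-letter bigram prime
#'
#' Describes which two word-internal letters form the prime, via either
#' explicit positions or a gap label: `"0L"` (adjacent), `"1L"` (one
#' intervening letter) or `"3L"` (three intervening letters). Positions must
#' be word-internal (neither the first nor the last letter).
#'
#' @param positions Integer vector of two 1-based positions, increasing; or
#'   `NULL` to derive them from `gap_label` starting at `anchor`.
#' @param reversed Emit the two letters in reversed order? Default `FALSE`.
#' @param gap_label One of `"0L"`, `"1L"`, `"3L"`, or `NULL`.
#' @param anchor First position used when deriving positions from
#'   `gap_label`; default 2 (the first word-internal letter).
#' @return An object of class `prime_spec`.
#' @export
prime_spec <- function(positions = NULL, reversed = FALSE, gap_label = NULL,
                       anchor = 2L) {
  if (is.null(positions)) {
    if (is.null(gap_label)) stop("either positions or gap_label is required")
    gap_label <- match.arg(gap_label, c("0L", "1L", "3L"))
    span <- c(`0L` = 1L, `1L` = 2L, `3L` = 4L)[[gap_label]]
    positions <- c(anchor, anchor + span)
  }
  positions <- as.integer(positions)
  stopifnot(length(positions) == 2L, positions[1L] < positions[2L])
  gap <- positions[2L] - positions[1L] - 1L
  if (!is.null(gap_label)) {
    expected <- c(`0L` = 0L, `1L` = 1L, `3L` = 3L)[[gap_label]]
    if (gap != expected) {
      stop(sprintf("positions (%d,%d) imply gap %d, inconsistent with label %s",
                   positions[1L], positions[2L], gap, gap_label))
    }
  } else {
    gap_label <- if (gap %in% c(0L, 1L, 3L)) paste0(gap, "L") else NA_character_
  }
  structure(list(positions = positions, reversed = reversed,
                 gap_label = gap_label, gap = gap),
            class = "prime_spec")
}

#' Bigram prime: two word-internal letters of the target
#'
#' Extracts the letters at the positions named by the [prime_spec()],
#' optionally reversing their order. Positions must be word-internal, so
#' the word must have at least 4 letters.
#'
#' @param word A letter string or character scalar.
#' @param spec A [prime_spec()].
#' @return Lowercase two-letter prime.
#' @examples
#' make_bigram_prime("ABOLISH", prime_spec(gap_label = "0L"))           # "bo"
#' make_bigram_prime("ABOLISH", prime_spec(c(2, 6), reversed = TRUE))   # "sb"
#' @export
make_bigram_prime <- function(word, spec) {
  w <- as_letter_string(word)
  stopifnot(inherits(spec, "prime_spec"))
  if (w$n < 4L) stop("word-internal bigram primes require a word of length >= 4")
  p <- spec$positions
  if (any(p <= 1L) || any(p >= w$n)) {
    stop(sprintf("positions (%d,%d) are not word-internal for a %d-letter word",
                 p[1L], p[2L], w$n))
  }
  l <- w$letters[p]
  if (spec$reversed) l <- rev(l)
  tolower(paste(l, collapse = ""))
}

#' All-letters-different (ALD) control prime
#'
#' Returns a prime sharing no letters with the target; errors on any
#' overlap. The candidate may be an arbitrary string or, as in two-letter
#' designs, the TL prime of another word.
#'
#' @param word Target letter string or character scalar.
#' @param candidate Proposed prime (character scalar).
#' @return Lowercase prime string disjoint in letters from the target.
#' @examples
#' make_ald_prime("ABOLISH", "we")  # "we"
#' @export
make_ald_prime <- function(word, candidate) {
  w <- as_letter_string(word)
  c_ls <- as_letter_string(candidate)
  overlap <- intersect(c_ls$letters, w$letters)
  if (length(overlap) > 0L) {
    stop(sprintf("candidate '%s' shares letter(s) %s with target %s",
                 c_ls$text, paste(overlap, collapse = ", "), w$text))
  }
  tolower(c_ls$text)
}

#' Build a stimulus table for a bigram-prime experiment
#'
#' For each 7-letter target word, constructs the requested prime conditions
#' (`0L`, `1L`, `3L`, `rev0L`, `rev3L`) at the canonical positions — `0L` at
#' (2,3), `1L` at (2,4), `3L` at (2,6) — plus an `ALD` prime drawn from
#' `ald_letters`. Returns one row per (target, condition).
#'
#' @param words Character vector of target words (length >= 4, typically 7).
#' @param conditions Character vector of condition labels to build.
#' @param ald_letters Candidate ALD primes tried in order until one is
#'   letter-disjoint from the target; defaults to a small pool.
#' @return Data frame with columns `target`, `condition`, `prime`.
#' @export
build_stimuli <- function(words,
                          conditions = c("0L", "1L", "3L", "rev0L", "rev3L", "ALD"),
                          ald_letters = c("we", "du", "ym", "ko", "vu", "xe")) {
  rows <- lapply(words, function(wd) {
    w <- as_letter_string(wd)
    prime_for <- function(cond) {
      switch(cond,
        `0L` = make_bigram_prime(w, prime_spec(gap_label = "0L")),
        `1L` = make_bigram_prime(w, prime_spec(gap_label = "1L")),
        `3L` = make_bigram_prime(w, prime_spec(gap_label = "3L")),
        rev0L = make_bigram_prime(w, prime_spec(gap_label = "0L", reversed = TRUE)),
        rev3L = make_bigram_prime(w, prime_spec(gap_label = "3L", reversed = TRUE)),
        ALD = {
          ok <- ald_letters[!vapply(ald_letters, function(a)
            any(as_letter_string(a)$letters %in% w$letters), logical(1))]
          if (length(ok) == 0L)
            stop(sprintf("no ALD candidate is letter-disjoint from %s", w$text))
          make_ald_prime(w, ok[1L])
        },
        stop(sprintf("unknown condition '%s'", cond)))
    }
    data.frame(target = w$text, condition = conditions,
               prime = vapply(conditions, prime_for, character(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
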