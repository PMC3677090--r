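---
title: "Letter-order coding models, match scores, and falsification by zero overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Letter-order coding models, match scores, and falsification by zero overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthoprime)
```

## The modelling problem

Visual word recognition must recover not only which letters are present
but in what order — anagrams such as CAT/ACT or TRAP/PART differ in
nothing else. The model family implemented here, *open-bigram coding*,
represents a word as an unordered set of ordered letter pairs: CAT is
{CA, AT, CT}. Its competitors code order differently: *slot coding* binds
each letter to its absolute serial position; *noisy-position* schemes let
each letter's perceived position be a Gaussian random variable; *gradient
(spatial) coding* represents order as a monotonically decreasing activation
profile over the letters.

Masked-priming experiments discriminate among these schemes through
**match scores**: normalized similarities in [0, 1] between a prime's and
a target's orthographic codes. The pivotal property is structural, not
parametric: when a scheme assigns a prime–target pair a score of *exactly
zero*, its code retains nothing of the target, so no downstream mechanism
could produce priming. A condition with score 0 but reliable observed
priming falsifies the scheme outright. `evaluate_models()` operationalizes
exactly this comparison.

## The coding policies

`coding_policy()` bundles the parameters that distinguish the open-bigram
variants:

| parameter | units | default | role |
|---|---|---|---|
| `max_gap` | intervening letters | 2 | the local-context constraint: a pair spanning three or more letters is not coded. `Inf` gives the unconstrained code used in textbook worked examples. |
| `include_edges` | flag | `FALSE` | boundary pairs `#C`, `A#` (weight 1). The headline counts in the literature exclude them, so off by default. |
| `gap_weights` | weight per gap, in [0,1] | `NULL` (binary) | `policy_seriol()` sets the distance weights 1.0 / 0.8 / 0.4 / 0: letters three or more apart are "too far apart to activate" the pair. |
| `noise_sd` σ | letter positions | 0 | Gaussian positional noise; 0 reduces every noisy computation to its noiseless counterpart. |

Pair identity is the letter pair alone; gap and edge status are
provenance. This set semantics is forced by the degenerate repeated-letter
case: the code of CASA, {(#C), CA, CS, AS, AA, SA, (A#)}, is fully
contained in that of CASACA, so `binary_ob_match("casaca", "CASA")` is
exactly 1.0 — the demonstration that strings with repeated pairs cannot be
distinguished by an unordered pair set. When a pair occurs at several
gaps, the stored weight is the maximum over occurrences (the closest
occurrence dominates, consistent with the distance-weighting rationale).
The published material does not fix how repeated letters should weight a
collapsed pair in weighted schemes; max-over-occurrences is this package's
choice and is applied uniformly.

For a no-repeat string of length $n$, the entry count has the closed form
$\sum_{d=1}^{\min(g_{\max}+1,\,n-1)} (n-d)$ (+2 with edges), which the
test suite verifies against brute-force enumeration. "Exhaustive" testing
over all no-repeat strings to length 8 is not literally enumerable
(26·25·…·19 ≈ 6×10¹⁰ strings), but pair extraction depends only on letter
positions and distinctness, so random relabelings per length cover the
structural cases; the suite uses 50 random no-repeat strings per length
2–8 under three policies.

## The match scores

All scores are normalized by the **target's** code (count or weight sum).
This is forced by the casaca→CASA = 1.0 example, which holds only under
target normalization; it also gives every model the two anchor properties
asserted across the test suite: identity primes score 1 and
letter-disjoint (ALD) primes score 0.

**Binary** (`binary_ob_match`): shared pairs / target pairs.

**Weighted** (`weighted_ob_match`): shared weight / target weight, a
shared pair contributing $\min(w_\text{prime}, w_\text{target})$. The
published description weights shared pairs by the target gap alone; the
two rules coincide whenever the shared pair is at least as close in the
prime as in the target — true for every prime type used in these designs
(two-letter, transposed-letter, substituted-letter, identity primes) — and
the min rule makes the weighted score the *exact* σ → 0 limit of the noisy
score, which the published description would violate for primes whose
pairs are more distant than the target's. We chose internal consistency.
A related open point: the literature reports SERIOL scores of .08/.07 for
the 0L/1L bigram primes where target normalization gives 1.0/11.6 ≈ .086
and 0.8/11.6 ≈ .069; the original normalization and rounding are not
stated, so the package reports full-precision values and does not force
agreement.

**Noisy-position** (`noisy_ob_match`): letter $i$'s perceived position is
$\mathcal N(i, \sigma^2)$, so the ordered pair at positions $i<j$ is
active with probability $\Phi\!\big((j-i)/(\sigma\sqrt 2)\big)$ and the
reversed pair with the complementary probability, each times the gap
weight of the physical separation. The match is the overlap
$\sum \min(a_\text{prime}, a_\text{target}) / \sum a_\text{target}$. The
min rule is this package's choice — the source material names no
combination rule — because it is bounded, symmetric in spirit with binary
intersection, and reduces correctly at σ = 0. Reversed-pair activation is
strictly increasing in σ and canonical activation strictly decreasing
(tested); the reversed probability is computed as `pnorm(-x)` rather than
`1 - pnorm(x)`, which would underflow to an exact 0 below σ ≈ 0.1 and
break the strict-positivity property. Default σ = 0.5 letter positions: a
round value giving reversal activations of the right order of magnitude;
published noisy-overlap scores (.27/.62 for two-/three-letter reversals)
come from a parameterization not reproducible from the available
description, so σ is exposed and `calibrate_noise()` fits it to published
scores by 1-D least squares (`optimize` over (10⁻⁴, 3]), reporting
residuals instead of asserting agreement.

**Slot coding** (`slot_coding_match`): aligned identical letters / target
length, left-aligned (the scheme's standard examples are equal-length;
left alignment is the natural extension and makes the subset prime
`pray`–PRAYS score 4/5). Note that anagrams can share fixed points: CAT
vs ACT scores 1/3 because the final T occupies slot 3 in both — slot
similarity is zero only for a full derangement such as TRAP vs PART.

**Gradient** (`gradient_match`): per-letter activation $d^{\,p-1}$ with
decay $d = 0.7$ per position (a stand-in: steep enough that the first
letters dominate, as the scheme requires, while 7-letter words retain
measurable tail activation; the full spatial-coding signal-weight match is
out of scope). Score: $\sum_{\ell \in \text{shared}} \min(a^P_\ell,
a^T_\ell) / \sum_\ell a^T_\ell$, repeated letters keeping their earliest
(strongest) activation. It preserves the scheme's ordinal predictions —
positive scores for any prime sharing letters with the target, and more
for a contiguous (`bo`) than for a distant (`bs`) bigram prime — but its
numeric values are not calibrated to published spatial-coding scores
(.22/.12), which come from the full model.

## Stimuli and the evaluation pipeline

`stimulus_builder` reproduces the designs' construction rules:
transposed-letter primes (`fo`–OF, `hte`–THE, `jugde`–JUDGE),
substituted-letter primes with replacements absent from the word
(`junpe`), two-letter bigram primes from word-internal positions — `0L` at
(2,3), `1L` at (2,4), `3L` at (2,6), optionally reversed — and
all-letters-different controls checked for zero letter overlap. The 3L
positions follow the worked example `bs`–ABOLISH, i.e. (2,6) with three
intervening letters; one passage of the source Methods says "position 2
and position 5", which contradicts its own example and is treated as a
typo. Which targets receive (2,3) vs (5,6) 0L primes is a user choice
(`build_stimuli` anchors at position 2); the packaged representative
stimuli use the published examples.

`load_priming_table()` ships the condition-level mean RTs (ms) and percent
errors of the three experiments, with a reliability flag per Same-trial
condition. Priming effects are control (ALD) RT minus condition RT over
Same trials only; Different trials show no masked priming in this task and
are stored but never analyzed. Because trial-level data are unavailable,
"observed priming > 0" defaults to "printed effect positive *and* flagged
reliable". One known discrepancy: the reversal cost printed for the
factorial experiment ("by 12 ms") comes from the fitted mixed model; raw
cell means give (29−18+25−13)/2 = 11.5 ms, and this package reports
raw-mean arithmetic throughout.

## The synthetic-data generator

`simulate_experiment()` emulates what the pipeline needs from trial-level
data of a cross-case same–different experiment, as a *stated world*, not a
fit to any dataset:

- **Scale.** Noise is Gaussian on invRT = −1000/RT, the analysis scale on
  which such data approximate normality; this yields right-skewed RTs
  without committing to a specific RT distribution family.
- **Structure.** invRT = baseline + subject effect + item effect +
  condition shift + residual, subjects and items crossed. Condition
  shifts apply to Same trials only; Different-trial condition means are
  equal by construction, mirroring the empirical null.
- **Injection.** Requested effects δ_c are in ms on the cell-mean scale.
  Because RT = −1000/invRT is convex, a first-order shift at the baseline
  inflates realized mean effects by ≈ 10% (Jensen's inequality; measured
  62.7 ms realized for 57 requested). The shift is therefore derived by
  numerically inverting the censored-normal expected mean RT
  (`integrate` + `uniroot`, censoring at the 2000 ms response deadline),
  making the injected effects unbiased — the property the recovery tests
  assert.
- **Defaults** are the two-letter arm of the first packaged experiment: 12
  subjects, 20 items, identity/TL/ALD with δ = 97/57/0 ms against a 477 ms
  baseline, published per-condition error rates, and variance components
  (subject 0.15, item 0.05, residual 0.35 invRT units ≈ 80 ms trial-level
  spread at baseline) chosen as plausible spreads; the source reports no
  variance components, so these are free generator parameters, not claims
  about any dataset.
- **Cutoff.** Generation and filtering are separate: `apply_rt_cutoff()`
  removes correct-Same analysis rows under 250 ms and reports the count.

`recover_effects()` estimates condition means over correct Same trials and
percentile bootstrap CIs by resampling *subjects* (the clustering unit;
with items crossed and balanced, item effects cancel in condition
differences). With 12 subjects a percentile interval is mildly
anti-conservative, which the calibration criterion absorbs: across 200
seeded replicates at this scale, the 95% CIs cover the injected effects in
≥ 90% of replicates (measured 91% identity / 94.5% TL).

What a green synthetic test does **not** establish: the generator has no
speed–accuracy coupling, no previous-trial autocorrelation, no
subject-by-condition slopes, and no sequential-sampling dynamics; it
validates the pipeline's arithmetic and calibration, not any cognitive
model of RT generation.

## Numerical and degenerate-input choices

- Scores are computed and stored at full precision; rounding to printed
  2-decimal conventions happens only in report formatting.
- A target with an empty code (length-1 string without edges, or
  all-zero weights) raises an undefined-score error rather than returning
  NaN.
- `count_open_bigrams()` is valid only for no-repeat strings;
  `normalize_string()` reports repeat status so callers can check.
- Exact-zero score tests use `tol = 1e-12` in `evaluate_models()`; the
  structural zeros are exact in floating point (empty intersections), so
  the tolerance only guards against degenerate user-supplied weights.
- CLI exit codes: 0 success, 1 validation error, 2 reference-value
  mismatch from `reproduce`.

## Known limitations

- The gradient coder is deliberately simplified; its numeric scores are
  ordinal stand-ins.
- The noisy-position model treats edge bigrams (when enabled) as
  noiseless.
- The falsification logic consumes condition-level summaries, not
  trial-level inference; it reproduces verdict patterns, not
  mixed-model coefficients (explicitly out of scope).
- Multi-word strings, letter-shape similarity, and lexicon-wide
  neighborhood effects are out of scope.
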