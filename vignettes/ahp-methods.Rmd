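---
title: "Prioritising user needs with the Analytic Hierarchy Process: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising user needs with the Analytic Hierarchy Process}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpelicit)
```

## The problem

Choosing or designing an expensive medical device — the running example
throughout this package is a multi-slice CT scanner for a public hospital —
requires knowing which user needs matter most, and to whom. Clinicians can
rarely quantify "how much more" they value patient monitoring over radiation
dose on an absolute scale, but they can answer a long series of small
questions of the form *"how important do you consider element i compared to
element j?"*. The Analytic Hierarchy Process (AHP) turns those pairwise
verbal judgments into a ratio-scale priority vector, screens each responder
for self-consistency, and lets profiles from different responders be
compared formally.

The package implements the full pipeline: hierarchy definition,
questionnaire design, judgment-matrix construction, eigenvector
prioritisation, consistency screening, two-level weight aggregation,
rank concordance between responders, and a synthetic-responder simulator
that validates every stage against known ground truth.

## The model

**Hierarchy.** Needs are organised in a fixed three-level tree: a goal,
categories beneath it, and need leaves beneath the categories. One judgment
matrix is elicited per comparison node: the goal node (comparing
categories) and each category (comparing its needs). The packaged
CT-scanner hierarchy has 4 categories (performance, safety, usability,
technical issues) with 3 needs each; a node of `k` children costs
`k(k-1)/2` questions, so a responder answers 6 + 4 × 3 = 18 questions.
Deeper trees are rejected rather than silently accepted, because the
aggregation below is defined for exactly two levels.

**Judgment matrices.** For a node with `n` children, the responder's
answers fill a positive reciprocal matrix `A` with `a_ii = 1` and
`a_ji = 1/a_ij`. If the responder were perfectly coherent,
`a_ij = w_i / w_j` for some latent weight vector `w`, which is equivalent
to the transitivity identity `a_ij = a_ik · a_kj` for every triple. Real
answers violate it, both through inattention and systematically — a
bounded integer scale cannot represent all products (2 × 3 = 6 exceeds a
five-point grid that stops at 5).

**Priorities.** The priority vector is the dominant (Perron) eigenvector
of `A`, normalised to sum to 1 — the *distributive mode*. For a transitive
matrix this recovers `w` exactly and the dominant eigenvalue λ_max equals
`n`; for inconsistent matrices λ_max exceeds `n`, and the gap is the raw
inconsistency signal. The package computes the eigenvector by power
iteration (positive matrices have a unique dominant positive eigenvector,
so no deflation is needed), declaring convergence when successive
normalised iterates differ by less than 1e-12 in max norm, with a 10,000
iteration budget; λ_max is read off as the sum of `A·w` at a sum-1 `w`.
The suite cross-checks this path against a dense eigendecomposition on a
thousand random reciprocal matrices (agreement within 1e-8).

**Consistency.** The consistency index is `CI = (λ_max − n)/(n − 1)`, and
the consistency ratio `CR = CI / RI(n)` compares it with the mean CI of
random matrices of the same size (the Random Index, a tabulated constant
for n = 1..9; RI(3) = 0.58, RI(4) = 0.90). The package follows the standard
`(n − 1)` denominator throughout: the shipped RI table and the
conventional CR ≤ 0.1 acceptance threshold are calibrated against that
form, so pairing them with any other normalisation would make the
threshold meaningless. A relaxed threshold of 0.2 is offered for settings
where re-elicitation is impractical; `CR` for `n ≤ 2` is defined as 0
(such matrices are always consistent). A responder failing the gate at any
node is flagged for re-elicitation and excluded from between-responder
comparisons unless explicitly included. The shipped RI constants come with
a Monte-Carlo re-derivation routine (`simulate_random_index()`); published
RI tables themselves vary by a few hundredths with the simulation design,
so its test asserts a sanity band, not printed-digit agreement.

**Aggregation.** The global weight of need *i* in category *m* is the
product of its local weight within the category and the category's weight
at the goal: `GW_i = LW_i^m · CW^m`. Since both levels are normalised
simplices, global weights sum to 1 over all needs.

**Concordance.** Agreement between two responders' profiles is Spearman's
rank correlation with mid-rank (average) ties, i.e. the Pearson
correlation of the rank vectors. Tie handling matters: published weight
tables are rounded to two decimals and routinely contain exact ties, and
mid-ranks are what makes printed concordance values reproducible from
printed weights. P-values are two-sided; for n ≤ 8 items the exact
permutation null is enumerated (all n! orderings, counting
|ρ_perm| ≥ |ρ_obs|), and for larger n the usual t approximation
`t = ρ√((n−2)/(1−ρ²))` on n − 2 degrees of freedom is used, falling back
to the enumeration bound `2/n!` when |ρ| = 1. The exact-enumeration path
assumes untied ranks (its inputs are the observed ρ and n only).

## The elicitation scale

Responders answer on a five-anchor verbal scale: *equally important* = 1,
*more important* = 3, *much more important* = 5, with reciprocals 1/3 and
1/5 for the "less" side. This deliberately compressed version of the
classic 1–9 scale is easier for responders unfamiliar with AHP, and after
distributive normalisation yields equivalent priorities. The package adds
in-between grades at ±2, ±1/2 (*slightly*) and ±4, ±1/4 (*moderately*),
giving the grid {1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5}; the exact verbal
labels for the in-between grades are a package convention, since only the
five anchors have canonical wording. The classic 1–9 grid is available via
`saaty_scale()` for studies that want it.

Questionnaire schedules counteract position bias: each element appears on
the left and the right of the question as evenly as possible (imbalance at
most 1 — perfect balance is impossible when an element appears an odd
number of times). Three-element nodes use the cyclic order (A,B), (B,C),
(C,A), so the final question is the redundant comparison implied by
transitivity from the first two and doubles as a coherence probe. For
larger nodes, pairs are emitted in lexicographic order with a greedy
orientation rule (the element with the lower left-minus-right count goes
left; ties keep the earlier element left), which is deterministic and
keeps the imbalance bound — the suite verifies this exhaustively for node
sizes 2 through 9. Answers given in flipped orientation are stored under
the scheduled orientation with the mirrored grade, and contradictory
duplicate answers are an error rather than being averaged: the remedy for
incoherent answers is re-elicitation, not silent repair.

## The synthetic-responder generator

The simulator exists to validate the pipeline, not to imitate any
particular clinical population. Each synthetic responder carries latent
priorities drawn from symmetric Dirichlet distributions — one simplex for
the categories, one per category for its needs. The default concentration
of 1 (uniform on the simplex) generates a broad range of profiles, from
near-uniform to sharply peaked, without favouring either; smaller values
mimic dominated profiles like an emergency clinician who puts 0.6 of the
weight on safety. Pairwise judgments are generated from the transitivity
identity itself: the noiseless judgment is the true ratio `w_i / w_j`,
perturbed multiplicatively as `a_ij = (w_i/w_j) · exp(ε)` with
`ε ~ Normal(0, σ²)` on the upper triangle only, the lower triangle forced
to exact reciprocals so the matrix stays valid at any σ. With quantization
on, each perturbed ratio is snapped to the nearest scale value in log
space (so a ratio and its reciprocal snap to mirrored grades) and the
stored entry is the grid value itself, keeping `a_ij · a_ji = 1` exact in
floating point.

Two regimes matter:

* **σ = 0, no quantization** — the identity test: every pipeline stage
  must invert exactly (CR = 0, recovered weights equal latent weights to
  numerical precision, ρ = 1 between responders sharing a profile).
* **σ > 0, quantized** — the realistic regime: the five-point grid alone
  (σ = 0, quantize on) already costs a mean L1 recovery error around 0.2
  on the 12-need CT hierarchy and leaves roughly half of uniform-Dirichlet
  responders inside the CR ≤ 0.1 gate; recovery error and mean CR then
  rise monotonically with σ (the suite checks this at σ = 0, 0.3, 0.6 with
  500 responders per level; `analysis/03_synthetic_validation.R` reports a
  finer sweep with 200 per level).

What the simulator does **not** model: responder fatigue and order
effects, systematic bias toward the left-hand element (the balanced
schedule exists to cancel a bias the generator never injects), and
structured intransitivity (the log-normal noise is symmetric and
unstructured). The log-normal perturbation is a modelling choice — the
source study reports no noise model for its responders — so passing
recovery tests shows the pipeline inverts this generator, not that any
particular clinical population would be this well-behaved.

Determinism: one integer seed fixes a simulation byte-for-byte. Per
responder and per node, the generator derives an offset 32-bit seed from
(simulation seed, responder index, node index), so any single responder's
data can be regenerated in isolation; generator calls save and restore the
caller's RNG state.

## The packaged study fixture

The package ships the printed tables of a published CT-scanner
needs-elicitation study with five senior clinicians (radiology, ear
surgery, elective neurology, emergency neurology, emergency medicine):
category weights, local and global need weights, per-questionnaire
consistency ratios, and the printed concordance cells. All values are
two-decimal printed numbers; the underlying raw judgment matrices were
never published. That has two consequences, both reflected in the code:

* `reproduce_study_tables()` checks only what printed values determine:
  the 60-cell aggregation identity |GW − LW·CW| ≤ 0.01 (printed-rounding
  slack), the seven printed need-level Spearman values within ±0.005
  before rounding, and the four printed category-level ρ = 1 cells
  exactly.
* The printed consistency ratios are display data. They cannot be
  recomputed from anything the package holds, so they are deliberately
  excluded from the reproduction checks; the consistency machinery is
  validated by the property suite on synthetic matrices instead.

One printed value is knowingly *not* matched: the study prints p = 0.040
for ρ = 1 on 4 categories, while exact enumeration gives 1/24 ≈ 0.0417
one-sided and 2/24 ≈ 0.083 two-sided. The package reports the exact
two-sided value by default (a one-sided option exists); under that
convention a perfect 4-item concordance is *not* significant at α = 0.05,
which is the mathematically defensible reading at n = 4. Note also that
with two-decimal weights several profiles are heavily tied (three of the
five responders tie all three safety needs), which inflates agreement
between otherwise different responders — the fixture's ρ = 0.73 between
radiology and ear surgery is largely a tie artefact, a known weakness of
coarse verbal scales.

## Numerical choices, in one place

* Power iteration: tol 1e-12 (max norm on normalised iterates), budget
  10,000 iterations; non-convergence is an error, not a silent result.
* CI is floored at 0 (λ_max can dip below n by rounding only); CR ≤ 2-item
  nodes defined as 0.
* Reciprocals are stored as one float per pair (`a_ji = 1/a_ij`), never
  converted twice; quantized entries are grid values, not
  `exp(log(grid))` round-trips — both keep `A ∘ Aᵀ = 1` exact.
* Identical rank vectors short-circuit to ρ = 1 exactly rather than
  trusting Pearson arithmetic at the boundary.
* Ranking ties in `rank_needs()` keep hierarchy order (stable sort) and
  are flagged, never broken arbitrarily.
* Exact permutation p-values are enumerated for n ≤ 8 (40,320
  permutations at n = 8, cached per n); beyond that the t approximation
  is used. At n = 8 the two agree to about 0.01 on average; the worst
  case over the discrete support is about 0.034, at large |ρ|.
* Weight tables are exported at full precision; two-decimal rounding is
  applied only in the human-facing display tables, mirroring the printed
  convention.

## Known limitations

* The two-level aggregation limits hierarchies to goal/category/need;
  deeper trees need recursive aggregation the package intentionally does
  not implement.
* Group consensus (aggregating responders into one weight vector) is out
  of scope; the concordance matrix describes agreement, it does not
  resolve disagreement.
* The exact permutation null assumes untied ranks; with heavy ties the
  reported small-n p-values are conservative approximations.
* RI constants cover n ≤ 9; larger nodes require a user-supplied RI —
  and a questionnaire that long is inadvisable anyway (the advisory
  machinery flags nodes above 4 children).
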