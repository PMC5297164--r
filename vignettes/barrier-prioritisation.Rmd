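---
title: "Prioritising implementation barriers from expert rank-order ballots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising implementation barriers from expert rank-order ballots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paretorank)
```

## The problem

Implementation studies routinely produce long lists of barriers that might
prevent clinicians from adopting an evidence-based practice. Resources to
address them are finite, so the barriers must be prioritised: which are most
worth targeting in an implementation intervention? `paretorank` operationalises
a structured, two-attribute answer. A multidisciplinary expert panel ranks,
for each target behaviour, all of that behaviour's candidate barriers twice —
once by *influence* (how strongly the barrier prevents the behaviour) and once
by *difficulty* (how hard it would be to overcome). Individual ballots are
aggregated into two group rankings per behaviour, and barriers are classified
by weak Pareto dominance into *most desirable*, *desirable* and *least
desirable* targets.

The bundled fixtures come from a published expert-panel survey on acute
stroke care in emergency departments: nine target behaviours (urgent triage,
thrombolysis eligibility assessment and treatment, temperature, glucose and
swallowing management, and rapid transfer to a stroke unit) with 53 barriers
in total, ranked by a 17-member panel of emergency and stroke nurses and
doctors, speech pathologists and bed managers. Each professional group ranked
only the behaviours within its area of practice, so ballot counts differ by
behaviour. The raw individual ballots of that survey were never published;
the fixtures carry its catalogue, its published group ranks with desirability
labels, its per-barrier median/IQR summaries, and a *synthetic* respondent
table constructed to reproduce the published marginal demographics exactly
(the joint respondent-level data are not public).

## Data model and elicitation contract

A ballot is a complete, tie-free ranking — a bijection onto `1..n_barriers` —
of one behaviour's barriers by one respondent for one attribute. The ranking
scale is therefore always exactly as long as the barrier list. Ballots are
stored in the raw elicitation direction (rank 1 = most influential, rank 1 =
most difficult to overcome) and converted on the fly to the canonical
reporting direction (higher = more influential, higher = less difficult):
influence ranks are reversed (`n + 1 − raw`), difficulty ranks are already
canonical. Keeping raw data raw makes the stored files auditable against the
original questionnaires.

Validation is strict: ties, gaps, partial ballots, unknown barriers and
out-of-range ranks are rejected with the offending respondent and behaviour
named. Ballots from a professional group that is not eligible for a behaviour
are an error by default (`on_ineligible = "drop"` downgrades this to a
warning, for exploratory use). A respondent may skip an eligible behaviour
entirely — whole-ballot absence is legitimate and aggregation simply uses the
ballots present.

## Individual summaries

Per-barrier medians and interquartile ranges of the canonical ranks use
`stats::median()` and `stats::quantile()` type 7 (linear interpolation
between closest ranks, R's default). The published summary table reports
half-integer medians, which pins down midpoint averaging for even panel
sizes but not the quartile rule; we fix the interpolated convention and
document it rather than guessing at an alternative. The published
median/IQR table is shipped as a reference fixture only: without the raw
ballots it cannot be recomputed, and it is deliberately not a test target.

## Aggregation: voting on the pairwise-majority graph

For each behaviour × attribute the ballots are tallied into a
pairwise-majority matrix `N(a, b)` = number of ballots ranking `a` strictly
better than `b`. Because ballots are tie-free, `N(a, b) + N(b, a)` equals the
number of ballots for every pair.

The consensus tool used in the original survey is described only as a robust
graph-theory-based voting system, so the concrete rule is this package's own
choice, exposed as a flag:

* **`schulze`** (default): beatpath strengths by Floyd–Warshall widest paths
  over winning-votes edge weights; each barrier scores one *win* per opponent
  it beats in the beatpath comparison. The beatpath relation is transitive,
  so win counts induce a total preorder consistent with it. Schulze is
  Condorcet-consistent, anonymous, neutral, and treats majority cycles
  symmetrically (a perfect three-ballot cycle comes out fully tied), which is
  exactly the behaviour wanted of a tie-permitting group ranking.
* **`copeland`**: pairwise wins minus losses; simpler, also symmetric, but
  coarser.
* **`kemeny`**: the exact Kemeny–Young order minimising total pairwise
  disagreement with the ballots, computed by dynamic programming over item
  subsets (Held–Karp on the linear ordering problem, feasible to the 9
  barriers that the largest behaviour has). Co-optimal orders are resolved
  lexicographically by barrier id, so the output is deterministic — at the
  price of neutrality on exactly-tied instances, which is why it is not the
  default. `kemeny_optima()` enumerates all co-optimal orders on small
  instances, mainly to detect non-uniqueness.

Group rankings are reported as tie-sharing integer *competition ranks counted
from the worst class*: a barrier's rank is one plus the number of barriers
strictly below it, so tied barriers share a value and a unique best barrier
gets `n_barriers`. The published group-rank table mixes tie conventions
internally (its tied pairs are not consistent with any single competition
scheme), which is one more reason the published ranks are treated as input
fixtures rather than recomputation targets.

A caveat worth stating plainly: Schulze and Kemeny–Young are different social
choice functions. On uniformly random ballot profiles with a unique Kemeny
optimum they produce the identical strict order roughly 95% of the time
(measured over seeded instances with 2–5 items in this package's validation
suite), and the package makes no claim of exact equivalence — a verified
4-item counterexample lives in the aggregation tests' design history. The
properties that *are* guaranteed, and property-tested at scale, are
unanimity, Condorcet-consistency, neutrality, anonymity, and (for Schulze)
monotonicity.

## Desirability classification

With canonical group ranks `(x, y)` per barrier, `a` **weakly dominates** `b`
iff `x_a ≥ x_b` and `y_a ≥ y_b` with at least one strict inequality. Weak —
not strict — dominance is the definition that reproduces the published
classifications, where barriers tied on one axis but beaten on the other are
classified as dominated; it also matches the stated principle that a barrier
scoring lower on one attribute *and no better* on the other is least
desirable. The three labels are:

* `most_desirable`: weakly dominates every other barrier;
* `desirable`: not most desirable, but weakly dominated by nothing;
* `least_desirable`: weakly dominated by at least one barrier.

Exact ties on both axes never dominate each other and always share a label.
One rule is an extrapolation: if a class of barriers tied on both axes
dominates all outsiders, the whole class is labelled `most_desirable`. No
such case occurs in the bundled data; the rule keeps the classifier total.
Dominance is a strict partial order (property-tested), labels are invariant
under strictly increasing transforms of either axis, and the classifier is
checked against an independently coded all-pairs oracle on thousands of
random point sets. Applied to the bundled published group ranks it reproduces
all 53 published labels, with exactly two behaviours possessing a
most-desirable barrier (fever protocols; blood-glucose machines).

## The panel simulator

Because the original raw ballots are unpublished, end-to-end validation runs
on synthetic panels. Ballots are drawn from a Mallows model: probability
proportional to `exp(−θ · d_τ)` where `d_τ` is the Kendall-tau distance to a
ground-truth order. Sampling uses the repeated-insertion method, which is
exact (tested against enumerated permutation probabilities): item `j` of the
reference is inserted at position `i ≤ j` with probability ∝ `exp(−θ)^(j−i)`.
Dispersion `θ = 0` is uniform; large `θ` reproduces the truth.

Defaults mirror the bundled survey's design: a 17-member panel (3 emergency
nurses, 3 emergency doctors, 3 stroke nurses, 3 stroke doctors, 3 speech
pathologists, 2 bed managers) with the same behaviour-eligibility masks, and
dispersion 2 — a moderately concordant panel, chosen once as a realistic
level of expert agreement (at `θ = 2` adjacent-pair inversions relative to
the consensus occur in roughly 12% of opportunities). Under those defaults
the whole pipeline recovers the planted top barrier of every behaviour in
over 95% of replicates (measured at 200 replicates per behaviour), and
planted Pareto structures (chains, anti-chains) are recovered exactly in the
noiseless limit.

What the simulator deliberately does not model: group-specific truths or any
other respondent covariate effects, missing-at-random ballot dropout, and
intensity information beyond rank order. Passing simulation-based tests
therefore demonstrates correctness of the machinery under a
consensus-plus-noise world, not that real panels satisfy that model.

## Numerical and design choices, in one place

* Percentiles: `quantile(..., type = 7)`; medians via `stats::median()`.
* Tie-to-rank conversion: bottom-up competition ranks (ties share; best
  unique barrier gets `n`).
* Determinism: any residual ambiguity (co-optimal Kemeny orders, summary
  ordering at equal medians) is broken lexicographically by barrier id.
* Plot jitter: exactly coincident points are offset by radius 0.1 rank units
  at an angle hashed from the barrier id — deterministic, bounded below 0.15,
  flagged with `*` in the figure.
* Axis limits fixed to `[0.5, n + 0.5]` so plots are comparable across
  behaviours; plotted coordinates are exposed pre-rendering via
  `behaviour_plot_data()`.
* Validation suite sizes (chosen as the package's own validation design):
  1,000 random profiles for the social-choice property suite, 200
  unique-optimum instances for the Schulze/Kemeny comparison, 50,000 draws
  for sampler exactness, 200 panel replicates for recovery, 1,000 point sets
  for the classifier oracle.

## Known limitations

* The package prioritises *perceived* influence and difficulty; it offers no
  trade-off weighting between the two attributes (deliberately — no such
  trade-off information is elicited), so a highly influential, hard barrier
  and a weak, easy one can both be merely "desirable".
* Group rankings from very small or strongly split panels can be largely
  tied; classification then labels most barriers desirable, which is honest
  but not very discriminating.
* Incomplete (partial-order) individual ballots are out of scope; only
  whole-ballot absence is supported.
* The published group ranks bundled here are inputs, not outputs: the
  original aggregation tool's internals (including its cycle and tie
  handling) are not public, so no attempt is made to re-derive them.
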