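---
title: "Exploring genetic interaction patterns with discrete Petri net models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring genetic interaction patterns with discrete Petri net models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petrigi)
```

## The question

When two regulators are deleted together, downstream genes can respond in
ways that no additive model predicts. Expression-based genetic interaction
profiling classifies these responses per gene: comparing the double-mutant
log2 fold-change $M_{x\Delta y\Delta}$ against the additive expectation
$M_{x\Delta} + M_{y\Delta}$ yields the classes *buffering*, *quantitative
buffering*, *suppression*, *quantitative suppression*, *masking* and
*inversion*. Inversion — the double mutant moving in the direction
*opposite* to the single mutants — is the most puzzling of these: unlike
buffering, which has redundancy as an obvious mechanism, no simple circuit
explains it at first sight.

petrigi asks the question exhaustively: over *all* three- and four-node
regulatory circuits built from two regulators (R1, R2) and two downstream
genes (G1, G2), with activating or inhibiting edges of two strengths, which
circuits produce which interaction patterns when simulated as discrete
Petri nets?

## The model space

Edges live in a 4×4 signed matrix (rows = sources, columns = targets) over
the alphabet $\{0, \pm 1, \pm W\}$, with $W = 5$ by default (weak = 1,
strong = 5) and $W = 9$ for a sensitivity analysis. Unconstrained there are
$5^{16} \approx 1.5 \times 10^{11}$ matrices; three structural conditions
make the space tractable:

1. no self-edges;
2. at most two incoming edges per node;
3. among the four regulator→gene edges, at least two that share a source
   regulator or a target gene.

Condition 3 is stated loosely in words; we adopted the *shared source or
target* reading because it is the unique predicate (among the natural
candidates we enumerated) that reproduces the published count of 9,287,616
admissible matrices. It excludes exactly the "crossing-only" case
(R1→Ga, R2→Gb with a ≠ b), which cannot couple the two deletions on a
common readout. The predicate is pluggable in `passes_conditions()` so
alternative readings can be counted against the same yardstick.

Enumeration is column-wise: conditions 1–2 leave 61 admissible
incoming-edge states per node, so the space factorises into
$61^2 = 3{,}721$ regulator-column pairs times $2{,}496$
condition-3-filtered gene-column pairs — $3{,}721 \times 2{,}496 =
9{,}287{,}616$. Each matrix is encoded as a 16-digit base-5 number (an
exact double), and all counting, mirror filtering and sampling works on the
column decomposition without materialising the space.

**Mirror filtering.** The labels R1/R2 and G1/G2 are arbitrary, so
matrices related by swapping the regulators and/or the genes describe the
same circuit. We keep the key-minimal member of each orbit of the order-4
relabeling group, giving 2,324,136 canonical matrices, which we verified
against an independent Burnside fixed-point count. The published figure is
2,323,936 — 200 fewer (0.009%). The original de-duplication procedure is
not described in enough detail to reproduce the difference; we report our
orbit count as computed and treat agreement within 200 as the expected
outcome.

**Logic expansion.** A node with two incoming edges needs a combination
rule. Each pair of incoming edges of equal weight *magnitude* generates two
model variants (AND and OR); pairs of different magnitude use OR only; and
when the two edges point in opposite directions, inhibition dominates in
both generated variants. The expansion factor is therefore $2^k$ with $k$
the number of equal-magnitude input pairs, giving 9,172,826 models
(published: 9,172,034; the difference is exactly what the 200 unresolved
orbits can carry). We initially considered keying the expansion on equal
*signed* weights, but that rule yields 4,900,080 models — half the
published figure — and was discarded; the equal-magnitude rule is the only
reading consistent with the printed total.

## Petri net semantics

Each node is a place holding tokens (its expression level); each edge
becomes a transition. Arc weights into transitions are always 1; the
weight on the output arc is the edge magnitude. Simulation runs 50
synchronous steps, and the G1/G2 token counts after step 50 are the
semi-quantitative expression read-out, compared across deletion conditions
via $M = \log_2\frac{\text{tokens}_{mut} + 1}{\text{tokens}_{WT} + 1}$
(the pseudo-count avoids division by zero).

The firing rules in full, as implemented in both the pure-R reference
(`compile_petri_net()`, `pn_step()`) and the compiled batch engine:

* **Provisioning.** A regulator receives 200 tokens (its mRNA resource
  pool, enough that three outgoing transitions cannot drain it in 50
  steps) unless the other regulator points an edge at it: a target of an
  activating edge is fed dynamically through that edge instead, and a
  target of an inhibiting edge starts empty. Downstream genes always start
  empty.
* **Activation.** An activating edge X→Y of magnitude w consumes 1 token
  from X per firing and delivers w to Y. Two activating inputs combine as
  one transition consuming from both (AND) or as two independent
  transitions (OR).
* **Constitutive sources.** A node whose only inputs are inhibitors is
  treated as constitutively transcribed: a source transition delivers
  `source_rate` tokens per step. The default rate equals the strong edge
  weight W — a constitutively active node is driven as strongly as a
  strong activating input — which also means the W = 9 sensitivity rerun
  rescales sources together with edges.
* **Inhibition dominates.** Every transition producing into a node is
  disabled while an inhibitor of that node holds at least one token (for
  the AND variant of a double-inhibitor node, only while both do).
  Inhibition is absolute while active, consumes nothing, and releases
  instantly when the inhibitor empties — in particular when the inhibiting
  regulator is deleted.
* **Deletion surgery.** A deleted regulator starts empty and every output
  effect into it is removed; its outgoing transitions are never enabled
  (no tokens), and its inhibitor gates are permanently inactive.
* **Maximal parallel firing.** Enablement is evaluated on the pre-step
  marking; all enabled transitions fire once. When simultaneous
  consumption demands exceed a place's tokens, enabled transitions are
  funded greedily in randomly shuffled order. This shuffle is the sole
  source of randomness: conflict-free nets are exactly reproducible under
  any seed, and models whose classified pattern tuple varies across the
  five repeated runs are flagged *unstable* and excluded from aggregates
  (strict unanimity; about 2.2% of models).

The worked anchor for these rules is the minimal inversion motif (weak
R1⊣R2, weak R1→G1, strong R2→G1):

```{r}
simulate_model(fig <- local({
  m <- matrix(0L, 4, 4); m[1, 2] <- -1L; m[1, 3] <- 1L; m[2, 3] <- 5L; m
}))
```

Wild type: R2 is silenced, G1 collects 1 token/step from R1 (50 tokens).
Deleting R1 releases R2, whose strong edge drives G1 to 245. Deleting R2
changes nothing (it was silent), and the double deletion starves G1
entirely — the inversion signature (+2.27, 0, −5.67).

**Why these rules.** The firing construction for inhibition and the
provisioning table are the least-documented part of the original method,
so the semantics above is a reconstruction, selected by behaviour: it must
(i) reproduce the motif trajectory and its classification, (ii) leave
exactly two minimal three-edge circuits showing inversion (the weak- and
strong-inhibition variants of the motif), and (iii) reproduce the
published aggregate statistics of the full survey. We explored the main
alternatives systematically — token-removal inhibition (with and without
consuming from the inhibitor), gating a node's outgoing rather than
incoming transitions, instant 200-token re-provisioning upon inhibitor
deletion, single-firing OR, and maximal-multiplicity firing — and scored
each against all published fractions. The chosen semantics reproduces the
unstable fraction (2.2% vs 2.3%), the scarcity of inversion without a
quantitative edge difference (1.4% vs 1.3%), the W = 9 persistence of
inversion (86% vs 85.4%) and the companion-buffering share (22% vs 23%).
Two statistics remain below the published values: the overall inversion
prevalence (≈1.35% of models vs 1.8%) and the share of inversion models
combining a quantitative edge difference with a buffering companion
(≈37.7% vs 41.0%). All alternatives we tested were further away on most
statistics simultaneously; we document the residual gap rather than
distort the semantics to close two numbers at the cost of the others.

## The pattern classifier

A gene interacts when $\varepsilon = |O - (M_1 + M_2)|$ exceeds the
threshold (log2(1.7) for simulated tokens, log2(1.5) for expression data;
the Methods-scale log2 value is used, not the raw fold-change). Direction
calls use |M| > log2(1.7) for simulations and adjusted p ≤ 0.01 plus the
sign of M for expression data — the caller is pluggable. With d1, d2, dO
the three direction calls and S the shared single-mutant direction, the
rule table (applied in order) is: buffering (d1 = d2 = 0, dO ≠ 0);
suppression (dO = 0, some single changed); masking (d1 = −d2 ≠ 0, double
within ε-threshold of the dominant single); inversion (dO = −S);
quantitative buffering (dO = S, deviation in the direction of S);
quantitative suppression (dO = S, deviation against S). The masking
boundary — "the double resembles the dominant single" — is the least
certain reconstruction and is isolated in a single predicate inside
`classify_gi()`. The table is total, deterministic, invariant under a
global sign flip and under swapping the two singles, and never fires on
additive observations.

## Survey analytics

`run_survey()` produces one row per model (stability, consensus patterns,
complexity, quantitative-difference flag); `inversion_by_complexity()`,
`co_pattern_distribution()`, `quantdiff_buffering_contingency()` and
`sensitivity_rerun()` compute the aggregate tables. Two conventions
matter:

* the companion of an inversion model is the other downstream gene (gene
  mirrors folded onto one orientation); models inverting in both genes
  count once and their companion is inversion, not buffering;
* the contingency analysis uses the buffering *superclass* (buffering or
  quantitative buffering) and a chi-square test with the Fisher fallback;
  for the all-models stratum a model qualifies when any patterned gene has
  a buffering-class companion, a symmetric definition under which
  independent flags show no enrichment (the null oracle in the test
  suite).

Exhausting all 9.17 million models is a batch job of a few hours on one
core; all distribution-level results in the package are computed on seeded
uniform samples of the expanded space (500,000 models in the acceptance
script, 200,000 in the test suite — sizes at which the binomial standard
error of every reported percentage is well below the tolerance it is
compared at). Sampling weights matrices by their logic-expansion factor,
so the sample is uniform over *models*, and per-model rng streams are
derived from (global seed, matrix key, variant), which makes chunked and
single-pass execution bit-identical — restartability is asserted in the
tests.

## Expression-side scoring

The expression module applies the same classifier to measured mutant-pair
profiles and adds the surrounding pipeline:

* **Growth scores.** $\varepsilon_{growth} = W_{xy} - W_x W_y$ on the
  fitness scale. Fitness is mutant-relative-to-wild-type, so slow growers
  sit below 1 and a synthetic-lethal-leaning double gives a negative
  score; the reciprocal convention would make negative interactions
  impossible for slow doubles, which is why we fixed this reading.
  Significance comes from a caller-supplied null mean/sd (the original
  background distribution construction is upstream of this package),
  one-sided for negative interactions, Benjamini-Hochberg adjusted.
* **Pair selection.** A pair enters analysis when its growth interaction
  is significantly negative and at least one single mutant is
  transcriptionally wild-type-like (fewer than eight genes with adjusted
  p < 0.05 and fold-change beyond 1.7).
* **Slow-growth correction.** Slow-growing mutants share an expression
  signature (the leading principal component of a large deletion
  compendium); `slow_growth_correct()` removes the orthogonal projection
  of a profile onto a supplied unit signature vector. Recomputing that
  component from the 1,484 external strains is out of scope — the vector
  is an input, and the synthetic generator provides one.
* **Clustering.** Pairs are summarised as pattern-count vectors (gene
  identity disregarded) and clustered with average linkage on
  1 − cosine similarity, on raw counts; leaf order is tie-broken by pair
  label, and dendrograms export to Newick.
* **Group statistics and enrichment.** Per-pair inversion percentages are
  compared with two-sided Mann-Whitney tests (BH across comparisons);
  gene-set enrichment uses the upper-tail hypergeometric test against a
  background of 6,359 genes with Bonferroni correction, with annotation
  sets supplied by the caller.

## The synthetic-data generator

`generate_pair()` plants, for each pattern class, (M1, M2, O) triples that
satisfy the class definition with a margin of at least twice the
classification threshold before noise (effect size 1.5 log2 units by
default — a typical clearly-regulated target), randomising the carrier
single mutant and the global sign. Unplanted genes are null. Measurement
noise is independent Gaussian on M values (sd 0.2 by default, the scale of
replicate-averaged microarray log-ratios); adjusted p-values are
synthesised from the known noise model rather than refit, since the
original limma statistics are upstream of this package. A smooth random
unit vector stands in for the slow-growth signature, added to all three
profiles with per-mutant loadings tied to 1 − fitness.
`generate_cohort()` mixes pair archetypes (buffering-dominated,
inversion-dominated, mixed epistasis) for cluster-recovery and
group-comparison tests.

What passing these tests shows — and what it does not: the generator
reproduces the *decision structure* of real profiles (margins, significance
coupling, a removable shared component, planted group structure), so it
validates the scoring, correction, selection and clustering machinery. It
does not emulate microarray intensity structure, replicate correlation,
gene-gene correlation beyond the signature, or the heavy tails of real
fold-change distributions, so classification accuracies on synthetic
cohorts are upper bounds, not forecasts, for real data. Cohort-specific
published figures (e.g. inversion percentages of particular gene families)
require the original microarray compendia and are deliberately not
reproduced here.

## Numerical choices and degenerate inputs

Matrix keys are exact integers below $2^{53}$ stored in doubles; orbit
minimisation, Burnside verification and seed derivation all operate on
them. Token counts are clamped to int range in the engine (unreachable
under the structural constraints). Zero-producer genes yield all-zero M
values and a `none` call; the all-zero matrix is rejected by the
structural conditions but simulates harmlessly. Cosine distances are
floored at 0 against rounding; all-zero pattern-count vectors are
rejected rather than silently placed. Exact Mann-Whitney p-values are used
where the implementation provides them (small samples without ties).

## Known limitations

* The firing semantics is a behaviourally validated reconstruction; the
  two residual aggregate gaps (inversion prevalence, the 41% contingency
  cell) are documented above and flagged red in the acceptance tests
  rather than absorbed into tolerances.
* The canonical count is the exact orbit count, 200 above the published
  figure, with the expansion total inheriting the same offset.
* Masking's boundary and the expression-side direction conventions follow
  this package's reading of the pattern definitions; both are isolated
  behind small, replaceable functions.
* The survey treats the two downstream genes as exchangeable read-outs;
  regulator-only patterns (e.g. interactions visible in R2's own level)
  are outside the read-out by construction.
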