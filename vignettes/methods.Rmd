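---
title: "Explaining black-box clinical predictions with class association rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Explaining black-box clinical predictions with class association rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleexplain)
```

## The two-model design

Accurate clinical risk models are usually opaque, and opaque models are
hard to adopt where clinicians must understand and defend decisions. The
design implemented here separates the two concerns: an arbitrary black-box
model makes the predictions, and a second, rule-based model — a class
associative classifier mined independently from the same training data —
explains them. The explainer never predicts. This matters statistically: a
patient often satisfies rules pointing at different outcome values, so a
rule set that would mispredict many patients (low sensitivity as a
classifier) can still *explain* nearly all of them, because explanation
only requires one applicable rule whose consequent matches the prediction.
The package demonstrates this asymmetry in its test suite with a small
constructed cohort where two conflicting rules cover all positives.

The explainer only contains rules for the *interesting* outcome values
(those requiring explanation); predictions of uninteresting values need no
explanation, and no rules are mined for them. There is deliberately no
guarantee that every positive prediction gets an explanation: rules capture
common patterns, and patients positive for idiosyncratic reasons may match
none. The evaluation metrics quantify exactly this.

### Assumptions on the data

* One row per patient; a feature table with typed categorical/continuous
  columns and a never-missing categorical outcome. Longitudinal
  aggregation ("past 3 years" counts, maxima, ...) is assumed to have
  happened upstream.
* A missing feature value never satisfies an item. This is a conservative
  choice: a rule never fires on unknown data, so no explanation is
  fabricated from absence of information. The alternative (imputation)
  belongs upstream of this package.
* Intervals are half-open `[lo, hi)`, so a set of cutpoints partitions the
  real line and exactly one bin matches any non-missing value; a condition
  like "BMI ≥ 35" is the item `[35, Inf)`, and a value exactly on a cut
  belongs to the right bin.

## Discretization

Continuous features are discretized supervised against the binary
indicator "outcome is an interesting value" — the same target the rules
aim to explain. The method is recursive entropy minimization with the
minimum-description-length stopping criterion: a split of `S` into
`S1, S2` is accepted iff

    Gain(S; T) > log2(N - 1)/N + Delta/N
    Delta = log2(3^k - 2) - (k Ent(S) - k1 Ent(S1) - k2 Ent(S2))

with `N = |S|` and `k, k1, k2` the numbers of classes present. Recursion
stops when the criterion fails, a side is pure, or a side has fewer than
two observations or distinct values; all-equal values or single-class
labels yield no cuts.

Numerical choices, all covered by oracle tests against a naive
re-implementation:

* Candidate thresholds are the midpoints between *all* adjacent distinct
  values, evaluated in one cumulative-count pass. The classical
  optimization of restricting candidates to class-boundary points gives the
  same optimum but leaves the tie case ill-defined; evaluating every
  boundary with an explicit tie rule is the better-specified contract and
  costs nothing at the sizes involved.
* Ties in information gain (within 1e-12) resolve to the smallest
  threshold. Identical values are grouped before boundary enumeration, so a
  tie in values can never straddle a cut.
* Cuts are placed at midpoints (rather than at either adjacent value) for
  symmetry.

## Rule mining

Rules are mined exhaustively by level-wise (Apriori-style) search over
antecedents built from the black-box model's features — using only those
features is itself the first pruning technique, since other features cannot
carry an explanation of that model's output. One item per feature is
allowed in an antecedent (two values of one single-valued feature are
jointly unsatisfiable), antecedents have at most `max_len` items, and a
candidate is extended only while its joint support with the consequent
stays at or above `min_support`. Joint support is anti-monotone, so this
pruning is lossless; confidence is not anti-monotone, so the confidence
threshold is applied only after counting. The output provably equals
brute-force enumeration (tested on random tables against an independent
enumerator).

Support uses the whole-cohort denominator (the joint proportion), matching
the convention of the associative-classification literature. When no
patient matches an antecedent, confidence is undefined and reported as
`NA`, never 0.

Defaults: `min_support = 0.01`, `min_confidence = 0.5`, `max_len = 4`.
These are the standard workable settings for class-association mining on
EMR-style tables: 1 % support keeps rules that cover a meaningful patient
group, 50 % confidence is far above typical outcome prevalences (an
interesting outcome near 19 % means a 50 %-confidence rule already more
than doubles the prior), and rules longer than four items are hard to
comprehend and act on. Determinism: items are ordered lexicographically by
(feature, value label) with locale-independent radix sorting, and rules
are generated in that order.

## The pruning cascade

Three stages run in a fixed order, each appending its surviving count to
the ruleset's provenance:

1. **Redundancy pruning.** A rule is removed iff a *retained* rule with the
   same consequent has a proper-subset antecedent and strictly higher
   confidence. "Strictly" follows the stated definition; an optional flag
   (`remove_equal_confidence`) also removes equal-confidence
   specializations, off by default since equal confidence is not "lower".
2. **Confidence-difference pruning.** The explanation-specific complement:
   a rule is removed iff a retained same-consequent generalization has
   confidence strictly *below* the rule's but within `delta` of it. Such a
   specific rule is non-redundant for prediction, yet redundant for
   explanation: the general rule covers every patient it covers, at almost
   the same confidence. At `delta = 0` this stage is the identity on
   redundancy-pruned input. Default `delta = 0.1`, the value at which the
   surviving-rule curve typically flattens.
3. **Whitelist filtering.** Only rules all of whose items a curator marked
   as plausibly outcome-related survive. A feature absent from a closed
   whitelist allows nothing; an explicit "open" mode disables the stage for
   uncurated runs.

Both subset-based stages process rules in increasing antecedent-size order
and allow only retained rules as pruning witnesses. This guarantees
*coverage preservation*: every removed rule leaves a surviving
same-consequent generalization with confidence at least
`removed − delta`, hence every patient covered by a removed rule is still
covered by a surviving rule. That guarantee is the point of the pruning
design and is property-tested on random rulesets.

A consequence worth knowing: with retained-only witnesses, the number of
survivors is *not* strictly monotone in `delta` in contrived cases — a
larger `delta` can remove a mid-sized witness and thereby spare several of
its specializations. Allowing removed rules as witnesses would restore
monotonicity but break the coverage bound above (witness chains could
drift more than `delta` below a removed rule). Coverage preservation is
the property the method's rationale rests on, so it wins; on realistic
rule populations the surviving count still falls steeply and essentially
monotonically as `delta` grows.

## Interventions and actionability

An *actionable item* is an item with at least one intervention in the
registry; a rule is *actionable* iff it carries at least one intervention.
The widget logic suggests, for each rule, all interventions registered for
its individual items; the curation step (accept/reject per rule) is modeled
as an optional per-rule selection, defaulting to accepting all suggestions
so the pipeline runs unattended. Annotation never changes rule statistics
or membership.

## Display

Applicable rules are sorted actionable-first, descending confidence within
each block, with deterministic tie-breaks (larger support, then canonical
antecedent label). Two diversified selection algorithms bound the display
at `n_r` rules (default 3):

* **Greedy disjoint** (default): take the top-ranked actionable rule, scan
  the rest, selecting rules whose actionable items are disjoint from all
  previously selected ones; if fewer than `n_r` are found, a wrap-around
  pass takes the earliest unchosen rules. Remaining slots are filled with
  non-actionable rules by the same procedure (judging disjointness over
  all items there, since non-actionable rules have no actionable ones).
  Being greedy and seeded with the top rule, it can miss an existing fully
  disjoint selection that excludes the top rule — e.g. top rule `{a, b}`
  followed by `{a}` and `{b}` at `n_r = 2`; the guarantee is that the
  first-pass selections are mutually disjoint and the top rule is always
  shown, not that the selection is a maximum disjoint set.
* **Weighted**: each actionable item carries its category's positive
  weight; a rule's weight is the sum over its actionable items. `n_r`
  passes each select the first-encountered maximum-weight unchosen rule,
  then zero its items' weights, steering later passes toward not-yet-shown
  items. Ambiguity about whether the wrap-around and fill steps should
  re-impose disjointness is resolved literally: earliest-first, no
  disjointness in the fallback.

The displayed set is always a subset of the applicable list; "view all"
is the applicable list itself.

## Evaluation

The probability cutoff maximizes Youden's J (sensitivity + specificity − 1)
over midpoints between adjacent distinct probabilities plus ±Inf sentinels,
classifying positive at probability ≥ cutoff; ties resolve to the smallest
cutoff, favouring sensitivity. AUROC is the exact Mann–Whitney rank
statistic with half credit for ties. The explanation metrics are: the
fraction of true positives (correctly predicted positives) with ≥ 1
applicable rule, the same restricted to actionable rules, the fraction of
*all* actual positives with ≥ 1 applicable rule (unconditional on the
prediction), mean applicable/actionable rules per explained true positive,
and mean *identified actionable items* — distinct actionable items across
all applicable rules of a patient, a measure of how much non-redundant
actionable information the rules carry. Identification counts all
applicable rules, not just displayed ones.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical shape the method consumes: a
mixed categorical/continuous feature table with planted high-confidence
rules. Features are sampled independently from their marginals; each
planted rule receives a disjoint random slice of the cohort (of size
`prevalence × n`) whose feature values are overwritten to satisfy the
antecedent — prevalences must therefore sum to at most 1, and overlap
between planted antecedents occurs only by chance. The outcome is drawn
per patient at the maximum `target_confidence` over the rules it actually
fires, or at `baseline_rate` otherwise; continuous features outside
planted antecedents then receive a class-conditional location shift so the
discretizer has a recoverable signal. The generator returns ground truth
(firing matrix and generating probabilities), and `standin_model()` turns
the generating probabilities into "black-box" predictions, blended with
uniform noise as `(1 − noise) p + noise U`; at zero noise it is a perfect
oracle.

The default configuration (`default_cohort_config()`) mirrors the intended
deployment scale: 9948 patients, three planted two-item rules with
confidences 0.65–0.75 styled on diabetes-risk patterns (ACE-inhibitor use
with BMI ≥ 35, loop diuretics with a high diagnosis count, statins with
age ≥ 65), and a baseline rate of 0.08, which brings overall outcome
prevalence to roughly 19 %.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: feature correlation beyond the planted
antecedents, missingness patterns, label noise correlated with features,
raw longitudinal structure, and the sheer feature dimensionality of real
EMR extracts (where mined rule counts reach the hundreds of thousands
before pruning). Results on the synthetic cohorts validate the machinery
and its statistical contracts, not clinical performance.

## Problem sizes in the test suite

The suite verifies mining against brute-force enumeration on thirty random
tables (n ≤ 300, up to 8 features), discretization and cutoff selection
against naive oracles on hundreds of random vectors, pruning coverage on
hundreds of random rulesets, parameter recovery of five planted rules
(confidences 0.60–0.90, prevalence 0.18 each) on 10 000-patient cohorts
over three seeds with tolerances of 0.03 on confidence and 0.02 on support
(2–4 binomial standard errors at the induced counts), and a noise-free
end-to-end run in which every true positive must be explained by a
confidence-1 rule. These sizes make every distributional check a
several-sigma event while keeping the default test run in the minutes
range.

## Known limitations

* Rule mining is exact and exhaustive; with many features and levels the
  level-wise search grows combinatorially. The intended regime is the
  tens of (model-used) features typical after feature selection, not raw
  thousand-column extracts.
* The manual curation steps (whitelist content, accepted interventions)
  enter only as data; the package does not attempt to judge clinical
  meaningfulness.
* Multi-instance patients, continuous outcomes (beyond thresholding
  upstream), and FHIR/OMOP ingestion are out of scope.
* The greedy display selection is a heuristic with the caveat described
  above; the weighted variant requires every actionable item to carry a
  weighted category and errors otherwise.
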