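---
title: "Adaptive event extraction: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive event extraction: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the pipeline model and its assumptions, the parameters that matter, what
the synthetic corpora can and cannot certify, and the numerical and design
choices made where the design was genuinely open. It states no empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

# The extraction model

An event is a typed predicate instance: a trigger span in the text, a set
of role-labelled arguments (entities or other events), and optional hedge
attributes. EventPipe decomposes extraction into four classification
problems run in order:

1. **Trigger/entity detection.** Tokens whose surface, base form, or stem
   appears in the training head-word table become candidates; each is
   classified into the annotation types recorded for that head form or a
   negative type. Tokens never observed as heads are not candidates — the
   model assumes lexical anchoring of triggers, which holds for shared-task
   annotation styles where triggers are words or nominalisations.
2. **Argument detection.** Every (trigger, participant) pair whose
   generalised type combination was observed in training becomes a
   candidate, classified into event role types (role names de-numbered at
   this stage). Participants include detected triggers, so nested events
   are reachable.
3. **Multi-argument detection.** For each trigger, every subset of its
   positively classified pairs whose role/argument-type multiset matches
   an observed event structure is classified into the structure label (or
   negative). Numbered roles live only here: the number expresses
   correspondence *between* arguments and cannot be predicted from a pair
   in isolation.
4. **Hedge detection.** Each assembled event is independently multi-label
   classified into {Negation, Speculation}.

All classifiers are one-vs-rest linear SVMs with squared-hinge loss. The
decision rule is multi-label: every label scoring above the separating
hyper-plane is selected, plus the highest-scoring label, with the negative
type participating as an implicit label of fixed score 0, so at least one
label is always chosen.

**Training on predictions.** Each stage's training candidates are generated
from the predictions of the preceding stages over the training documents,
not from gold annotations. A candidate that coincides with a gold
annotation (trigger token, argument references, and de-numbered roles all
equal; numbered roles at the multi-argument stage) inherits its label;
every other candidate gets the negative type. This aligns the training
distribution of each detector with what it will see at prediction time;
the cost is that errors early in the pipeline propagate into the later
stages' training sets.

# Adaptation objectives

With `loss(x_i) = max(0, 1 − y_i·w·x_i)²` the four training objectives
are:

| mode | objective |
|------|-----------|
| plain | `w'w + C Σ_i loss_i` |
| weighting | `w'w + (n_n/n_p) C Σ_p loss + C Σ_n loss` |
| covariate shift | `w'w + C_CS Σ_i l(x_i) loss_i` |
| combined | `w'w + (Σ_n l/Σ_p l) C_CS Σ_p l loss + C_CS Σ_n l loss` |

`l(x) = (n_train/n_target) p_target(x)/p_train(x)` is the target-to-train
density ratio estimated by a ridge logistic regression separating training
from target candidate vectors, and `C_CS = n C / Σ_i l(x_i)` rebalances
the loss term after weighting.

Two reduction identities pin the algebra down: with all `l(x) = 1` the
covariate-shift objective *is* the plain objective and the combined
objective *is* the weighted one (and `C_CS = C`). The combined form is
written so that these reductions are exact — the `(Σ_n l/Σ_p l)` ratio
multiplies only the positive-loss term, which is the unique placement
consistent with reducing to the weighting objective at unit weights. The
test suite asserts both identities over randomly drawn weight vectors and
batches at `1e-12` tolerance.

The point of these objectives is to *remove* hyper-parameter search: `C`
is fixed at 1 everywhere, and the weighting/balancing constants are
computed from the data, never tuned.

# Parameters

All defaults live in the task configuration (`taskConfig()` /
`parseTaskConfig()`); values are dimensionless unless noted.

* `C = 1` — SVM cost. Fixed by design; exposed only for completeness.
* `hashBits = 20` — feature-space exponent (indices in `[0, 2^20)`).
  Hash collisions act as mild regularisation; 2^20 makes them rare at
  shared-task corpus sizes. The package's own synthetic experiments use
  2^12, matching their much smaller vocabularies and keeping the dense
  per-label weight vectors small.
* `charNgram = c(2, 4)`, `wordNgram = c(1, 3)` — n-gram orders for the
  lexical feature families. Conventional relation-extraction ranges; the
  feature families matter more than the exact orders.
* `clip = c(1e-3, 1e3)` — bounds on the estimated density ratio `l(x)`
  before `C_CS` is computed. Ratio estimates from a finite-sample domain
  classifier have heavy tails; clipping caps any single instance's
  influence at three orders of magnitude.
* `pairCap = 10` — argument pairs kept per trigger (highest decision
  scores) before subset enumeration, bounding the 2^k combination blow-up.
* Domain classifier: ridge penalty `1/n` (unit strength on the summed
  log-likelihood scale) with 5-fold cross-fitting, so every instance's
  probabilities come from a model that never saw it — without
  cross-fitting the in-sample ratios are systematically overconfident.
* `mode` — `none`, `weighting`, `covariate_shift`, or `combined`.
  `weighting` is the recommended default for ordinary training: candidate
  classification is heavily imbalanced (most candidates are negative), and
  the weighted objective is what keeps recall usable. The covariate-shift
  modes additionally require (unlabelled) target-domain documents.

# The synthetic corpus generator

`synthSpec()`/`generateCorpus()` build standoff corpora from fixed token
templates: a one-Theme expression event, a two-Theme binding event
(exercising numbered roles), and a regulation event with an optional Cause
that may nest an expression event as its Theme. Hedge cue words attach
Negation/Speculation with probability 0.15 each; 30% of sentences are
event-free distractors that reuse trigger head forms (the class-imbalance
control); 20% are plain filler. Sentences carry a trivial left-branching
dependency parse, so gold dependency paths are known exactly and no
external parser is needed. Train-vs-target covariate shift tilts the
sampling distributions of trigger forms and context words (entity surfaces
shift too, but entity masking erases them from the feature space by
design — the shift the domain classifier sees is lexical context).
Generation is a pure function of the spec: the same seed yields
byte-identical corpora.

The generator's templates are deliberately unambiguous: every trigger form
is disambiguated by its sentence context, and role assignment follows
textual order. A pipeline that reaches strict-match F ≥ 0.95 on held-out
synthetic documents (the learnability check in the acceptance suite, run
at 200 training documents, 2^12 hash dimensions, weighting mode)
demonstrates that the candidate generation, feature extraction, training,
and assembly machinery are correct end to end — it does **not** certify
performance on real text, where triggers are ambiguous, parses are noisy,
structures are rarer and longer-tailed, and annotation is inconsistent.
Scores on real shared-task corpora require those corpora and a real
syntactic parser through the parse interchange format.

# Numerical choices

* **Optimiser.** The objectives are smooth (squared hinge) and strictly
  convex in `w` (the `w'w` term), so the trainer is an L-BFGS run started
  at the origin with analytic gradients — deterministic, no restarts
  needed. Convergence: relative-objective tolerance 1e-6 equivalent
  (`factr = 1e4`), 10,000-iteration cap. The test suite checks the
  attained objective against an independent numeric minimiser (different
  algorithm, numeric gradients, multiple starts) at a 1e-4 relative gap
  on small problems.
* **Hashing.** 32-bit MurmurHash2 over `group ⊕ key`, implemented in the
  package's own C++ so indices are identical across platforms and between
  training and prediction; the model archive records the hash choice and
  loading a model with a mismatched hash errors. Collisions sum. Each
  feature group's sub-vector is scaled to unit Euclidean length, then the
  whole vector is scaled to unit length again, so no family dominates by
  raw count.
* **Shortest paths.** Breadth-first search over the undirected dependency
  graph of one sentence; among equal-length paths the lexicographically
  smallest token-index sequence wins (determinism). Cross-sentence pairs
  have no path and degrade to distance-bucket features, and are enumerated
  at all only when the training inventory observed that combination across
  sentences.
* **Ties in the decision rule.** All labels tied at the maximum score are
  returned; scores are deterministic, so so are ties.
* **Degenerate inputs.** Empty corpora, zero-event corpora, empty feature
  sets (zero vector), labels with no positive instances (no scorer is
  trained; the label can then never be predicted), and single-class
  domain-classification folds (an error) are all handled explicitly.
* **Zero denominators in scoring.** Recall is 1 when gold and predicted
  are both empty, 0 when only gold is non-empty; precision symmetrically;
  F = 0 when P + R = 0.

# Design decisions in open territory

* **Soft-boundary matching** is operationalised as: a predicted span
  matches a gold span lying within the gold span extended by one token on
  each side (exact equality always matches). **Partial recursive
  matching** relaxes event-valued arguments: the sub-event matches if its
  type and trigger soft-match and its Theme-role sub-arguments match
  recursively, ignoring other sub-arguments. Both are reconstructions of
  shared-task conventions, isolated behind the `mode` flag of the scorer
  (`strict` / `partial`) so they can be swapped against an external
  evaluator.
* **Generalisation and label position.** Which generalisation applies
  depends on where a name sits in a label: the regulation/PTM collapses
  act on trigger types, the EVENT/ENTITY catch-alls on argument types, and
  de-numbering on roles (retained inside structure labels, where numbers
  carry the argument correspondence). `generalizeType()` therefore takes a
  `position` argument alongside the `context`; an explicit `Name -> Group`
  rule always wins over a catch-all.
* **Instance-generation expansion** (`expandStructures()`) duplicates
  observed structures across rule-sibling event types at prediction time
  only. Expanded labels have no trained scorer of their own; they borrow
  the source label's scorer, and the emitted event's type always comes
  from the predicted trigger, not from the (possibly generalised) label.
  Rules are restricted to event types: sharing structures across unrelated
  types can manufacture type-illegal events, which is why expansion is a
  separate, opt-in mechanism rather than part of label generalisation.
* **Nested-event assembly** is a bottom-up fixpoint: an event whose
  argument is a trigger token only assembles once that trigger has an
  assembled event; when several exist the first in document order is
  referenced; exact structural duplicates are deduplicated; candidates
  whose sub-events never assemble are dropped. Cycles are impossible by
  construction.
* **Numbered-role assignment** at emission follows textual order: within a
  role group, slots ordered by number are zipped with arguments ordered by
  start offset. The synthetic generator uses the same convention, and for
  natural corpora it matches the dominant annotation style.
* **Trigger candidates never overlap gold entity spans.** The alternative
  (allowing triggers inside given entities) is conceivable for schemes
  with entity-anchored events, but it complicates the masking step and
  was not needed for the target schemes.
* **Head word of a multi-token span**: the token whose dependency head
  lies outside the span when a parse exists, else the rightmost token — a
  standard approximation; no fallback is claimed to be linguistically
  correct.
* **Stemming** is a compact rule-based English suffix stripper behind the
  `stemWord()` interface; the head-word table only needs a stable surface
  normalisation, and the interface allows substituting a full stemmer.
* **Structure-stage features** include the roles and types of the pairs
  *excluded* from a candidate combination. Whether a `{Theme}` combination
  is a complete event depends on what else the trigger could have bound;
  the excluded-pair features make that evidence explicit instead of
  leaving it implicit in context n-grams.

# Known limitations

* The pipeline is greedy: no joint decoding, no beam over stages, and no
  recovery from a trigger the first stage missed.
* Stacked models over external corpora are out of scope; the
  `stack_score` feature group is reserved as an integration hook.
* Discontinuous trigger spans are rejected at parse time.
* Coreference, relation (`.rel`) annotations, and ontology-driven
  generalisation discovery are out of scope.
* The fallback tokenizer's left-branching parse makes dependency-path
  features degenerate to surface adjacency; for real text, supply a parser
  through the parse interchange format.
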