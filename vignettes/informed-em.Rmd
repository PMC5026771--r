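---
title: "Event extraction with annotation-adjusting Informed EM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event extraction with annotation-adjusting Informed EM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioevent)
```

This vignette is the package's account of its science: the graph encoding
of biological events, the linear structured model and its exact decoder,
the two training algorithms, the four posterior constraints, the design of
the synthetic corpus generator, and every numerical convention that a
reader reproducing the results needs to know.

## Task and representation

The extraction target is the GENIA Event Task 1 vocabulary: nine event
types in three groups — plain protein-taking events (Gene_expression,
Transcription, Protein_catabolism, Phosphorylation, Localization; exactly
one protein THEME), multiple protein-taking events (Binding; one or more
protein THEMEs), and event-taking events (Regulation,
Positive_regulation, Negative_regulation; one THEME that is a protein or
an event, at most one CAUSE). Inputs are BioNLP'09-style standoff files
(`.txt`, `.a1`, `.a2`) plus per-sentence lexical analyses and basic
Stanford dependency parses; parsing itself is out of scope, parses are
data. Multi-word protein mentions are merged into single tokens, with
their internal dependency edges dropped and crossing edges redirected.

Events are encoded per sentence as a labeled directed graph. A possibly
multi-word trigger is represented by a single **anchor word** — by default
the trigger's syntactic head (the in-span token whose governor lies
outside the span; ties to the rightmost). Exact trigger spans are
deliberately not modeled; context features are expected to carry the
information in the other trigger words. A node may hold several type
labels (sentence patterns like "mRNA and surface expression" anchor
Transcription and Gene_expression at one word), and each ordered word
pair holds at most one role. Two structural facts need special care:

* **Loops.** A Positive Regulation event sharing its trigger with the
  Gene Expression event it regulates produces a self-loop. Such GE/PR
  pairs are replaced by one node with the composite label
  `Gene_expression/Positive_regulation` (a *merged event*), which expands
  back to the pair on conversion; CAUSE edges of the merged node attach
  to the regulation component, which carries the causal semantics. Other
  loops (e.g. from hyphenated protein–trigger tokens) are removed; a node
  that thereby loses its last THEME edge cannot be encoded and its labels
  are dropped. Composite labels are an open set — any two types may
  co-label a node — but only the GE/PR composite triggers merged-event
  expansion.
* **Cycles.** A cyclic role-edge graph would generate unboundedly many
  nested events; such sentences are discarded on the gold side and
  yield no events on the prediction side.

Converting gold annotations to graphs and back
(`reconstruct_annotations()`) measures exactly what this encoding loses.
Recorded gold trigger spans are restored on the way back, so the
comparison isolates structural loss (discarded cycles, removed loops,
over-generated conversions) from span normalization. On generated corpora
containing merged-loop sentences the round trip is lossless with merged
events and lossy without them, in both directions the reconstruction
experiment expects: recall drops where the regulation label loses its
THEME, and precision drops where it degrades to a protein-THEME
regulation.

Conversion back to events proceeds in topological order. One contract was
genuinely open: for event-taking nodes we emit one event per THEME target
crossed with the available CAUSE targets, and emit a CAUSE-less event
*only when the node has no CAUSE edge*. Always adding the CAUSE-less
variant would break round-trip identity (a gold regulation with a CAUSE
would reconstruct as two events). Similarly, all THEME protein edges of
one Binding node form a single event — the simplest contract consistent
with "one or more proteins as THEME".

## Features

Word vectors `Φ(x_i)` contain surface/baseform/POS indicators; per-type
lexicon reliabilities as real values; center-marked n-grams (n = 2–4)
over `baseform:POS` pairs with protein mentions rendered as `PROTEIN`,
the center token bracketed, and explicit boundary symbols at sentence
edges; binary `Protein-Distance:d` indicators; `Trigger-Distance:d`
features valued at the other candidate word's best reliability; and
governor/modifier features per dependency edge. Distances skip
punctuation tokens — the convention that makes the three printed
distances of the motivating examples mutually consistent (5 and 2 within
"express either decreased or increased numbers of VDR"; 4 between
'levels' and 'augmented' across a comma).

Two conventions deserve a note because the obvious alternatives are
inconsistent with the worked examples this package reproduces:

* Governor/modifier features are emitted in **two renderings** — self
  token as `baseform:POS` and as `surface:POS` (the other token always as
  baseform) — producing both `number:NNS-MOD(amod)-decrease:VBN` and
  `numbers:NNS-GOV(dobj)-express:VBP` for the word 'numbers'.
* Dependency-path steps are rendered from the **perspective of the
  path-interior node**: its view of the neighbour is `GOV(rel)` if the
  neighbour governs it, `MOD(rel)` if the neighbour modifies it (the
  right node supplies the perspective for the first step, the left node
  afterwards). This yields `MOD(amod) GOV(dobj)` for the path
  decreased→numbers→express, which no step-local direction-of-travel rule
  can produce. Ties among shortest paths go to the lexicographically
  smallest token-index sequence.

Pair vectors `Φ(x_i, x_j)` add both endpoints' word features (namespaced
by endpoint), a path-length indicator, and n-grams (n = 2–4) plus the
full sequence of three path renderings: token, dependency, and
interleaved token-dependency.

## Trigger lexicons and candidate filtering

Constituent words of annotated triggers are counted per event type;
hyphenated words contribute their components and the original. The
reliability \(R_{w,e} = C_{w,e}/C_w\) divides by *all* token occurrences
of the entry in the corpus — a precision-like ratio, which is why the
denominator is not restricted to trigger-internal occurrences (the open
counting question is resolved toward token occurrences, not document
frequencies). Entries and lookups are lower-cased; casing of biomedical
trigger words is too variable to be a reliable signal. Entries with
reliability strictly below 1 % are pruned. A stemmed lexicon (Porter
algorithm, implemented in the package and tested against the published
worked examples) is built alongside, and candidate lookup max-pools over
surface, baseform, hyphen components, and stems.

Words with no lexicon entry are fixed to 'negative'; admissible edges run
from a candidate word to a protein token or another candidate. The
per-type refinement of the edge-target condition ("events that take
proteins") is deliberately simplified to "any candidate": all nine types
can take a protein as THEME or CAUSE, so the refinement would prune
nothing on this label set.

## Model, decoding, and numerical conventions

The assignment score is the sum of node scores (±`w_e · Φ(x_i)`, the
negative label scoring the exact negation) and edge scores (`w_L ·
Φ(x_i,x_j)` with a separate weight vector for the negative edge label),
subject to two validity conditions: positive words need an outgoing THEME
edge, and role edges must leave positive words. Both conditions couple
only labels sharing a source token, so exact decoding decomposes per
source token:

1. **Pass 1 (exact).** For each candidate word, compare the non-anchor
   option (all labels negative) with the best anchor option: each type
   takes its better label with the least costly type forced positive if
   all prefer negative; each out-edge takes its argmax label with the
   least costly edge forced to THEME if none prefers it (forcing cost =
   best label score minus THEME score; ties to the smallest target
   index). Exact score ties resolve to 'negative'/non-anchor, which makes
   zero-weight decoding deterministic and biases toward precision. The
   test suite checks this pass against exhaustive enumeration of all
   valid assignments on hundreds of random instances.
2. **Pass 2 (refinement to fixpoint).** The target-side condition (role
   edges must *end* at anchors or proteins) would break the per-token
   decomposition, so it is enforced afterwards: offending edges are
   relabeled negative and anchors losing their last THEME are demoted,
   iterated until stable (at most one demotion per token, so at most
   `|tokens|` iterations).
3. **Pass 3.** If the remaining role edges contain a cycle the sentence
   yields no events.

`INVALID` assignments score `-Inf`, which is also how they are compared
inside learning.

## Learning

**Baseline (cost-sensitive Passive-Aggressive).** Weights start at zero;
20 passes in fixed document order (no shuffling — the seed only controls
data generation, keeping training bit-reproducible). On each mistaken
sentence the closed-form PA step `w ← w + τΔ`, `τ = max(0, score(pred) −
score(gold) + cost)/‖Δ‖²`, enforces a margin of exactly the incurred
cost, with false negatives costed 3.8 times false positives and a role
substitution counted as one of each. Mistakes are detected, and updates
computed, against the pass-1 argmax — the assignment the model actually
maximized. After every pass the running average of all interim weight
vectors is stored (implemented by the lazy accumulator
`avg_T = ((T+1)W_T − U)/T` with `U = Σ t·δ_t`, verified against explicit
accumulation in the tests). Gold graphs whose mask-restricted assignment
is invalid (a gold trigger outside the lexicon candidates) are skipped
rather than chased toward an unreachable target.

**Informed EM.** The adjusted annotation set starts at the gold graphs.
Rounds 1–5 are M-steps only (identical to the baseline — random
initialization would make the Viterbi approximation converge to poor
local optima). From round 6 each round first decodes every sentence with
the current interim (non-averaged) weight vector — the same vector the M
step updates, which makes the degenerate case exact: with α above any
achievable score ratio the entire run is bit-for-bit the baseline. A
prediction replaces the current adjusted graph only if it differs and
passes all active constraints:

* **basic** — identical typed structure (event types present, and
  (parent type, role, child kind) triples with protein arguments compared
  by mention id and event arguments by type) to the *gold* graph;
  triggers are free to move;
* **confidence** — `(cand − cur)/max(|cur|, 1e-8) ≥ α`; the ε floor
  keeps the relative criterion defined near zero scores; both scores are
  recomputed under the current model each round;
* **non-overlapping** (optional) — per type, at least as many distinct
  candidate anchor words as distinct gold trigger *spans* (two events
  sharing one gold trigger need only one anchor); composite labels count
  for each component;
* **distance** — every anchor of type e in the *current adjusted* graph
  must have a candidate anchor of type e within β word tokens. Only this
  direction is enforced; the reverse binding is not implied by the
  two-trigger worked example that motivates the constraint.

Updated sentences keep their flag permanently and are trained with the
error cost multiplied by 10 — treating the adjusted graph as a small
trusted domain the model must fit, as in instance-weighting domain
adaptation. Persistence (rather than a one-round boost) is a design
choice: an adjusted graph remains non-gold forever, so its extra weight
should not silently expire. An audit log records every accepted update
with both graphs and both scores; the acceptance tests re-check every
logged update against independently re-evaluated constraints.

Tunable constants, with defaults: passes 20; init rounds 5; false
negative cost ratio 3.8; updated-sentence cost multiplier 10; α = 0.3
(dimensionless relative score improvement); β = 2 word tokens. The best
constraint configuration is reported in the source analyses as α = 0.3
with β = 2 (a stray "β = 0.2" in prose is read as a typo for 2 — β counts
word tokens and the relaxed comparison setting is β = 100); model
selection takes the best round after the initialization rounds on a
held-out set.

Setting `use_basic = FALSE`, `alpha = -Inf`, `beta = Inf`,
`use_noc = FALSE` disables every gate and gives the pure (unconstrained)
Viterbi EM, which accepts a superset of the constrained updates in the
first E step and serves as the degradation control.

## Evaluation

Event matching is greedy, deterministic (gold ordered by trigger offset,
type, id) and one-to-one. `exact` requires type, trigger span and full
recursive structure; `approx_span` lets the predicted trigger lie within
the gold span extended one word each side (located in the document text);
`approx_recursive` additionally compares nested event arguments on type
and THEME only. Conventions: a 0/0 ratio counts 1.0; F1 is 0 when
recall + precision is 0. Training runs are compared pass-by-pass with a
one-tailed paired t-test (H1: mean difference > 0); zero-variance
differences degenerate to p = 0, 1, or 0.5 (all-zero differences being
the t = 0 boundary).

## The synthetic corpus generator

Five sentence families with template-derived dependency trees (no parser
anywhere in the pipeline): plain events ("PROT was expressed in T cells
."), nested regulations ("PROT1 induces the expression of PROT2 .",
optionally with a protein CAUSE, probability 0.4), multi-word-trigger
regulations ("PROT1 showed increased levels of PROT2 ."), Binding
("PROT1 binds PROT2 ."), and merged GE/PR loops ("PROT was overexpressed
in T cells ."). Default mixture weights (0.25 / 0.2 / 0.3 / 0.15 / 0.1)
keep the inconsistency-eligible multi-word family prominent, since it is
the phenomenon under study. Trigger vocabularies overlap across types
("expressed" serves Gene_expression and Transcription) to exercise
multi-label anchors; the protein pool contains hyphenated and multi-word
names to exercise hyphen splitting and mention merging. Every generated
corpus is assembled as standoff text and read back through the package's
own parsers, so format validity is enforced by construction, and
generation restores the caller's RNG state.

**Span inconsistency** emulates the motivating ambiguity: eligible
triggers are the multi-word ones ("increased levels", head-word
convention); a seeded fraction is re-annotated as the bare modifier
("increased"), leaving text and event structure untouched. Under the
Head-Word rule the two conventions anchor at different tokens, which is
precisely the training-signal conflict the Informed EM constraints allow
the model to repair. The default study condition uses a rate of 0.3 on
300 sentences, with held-out corpora generated clean (rate 0) and
normalized to anchor-level gold via the graph round trip, because decoded
events can only carry anchor-word spans — the held-out comparison is
therefore about structure and anchoring consistency, not span recovery.

What the generator does **not** emulate: real biomedical syntax (template
trees are short and regular), parser noise, cross-sentence events,
annotation errors other than span-convention flips, and the long-tailed
trigger vocabulary of real corpora (lexicon reliabilities here are high
and pruning removes little). Passing tests therefore demonstrate
correctness of the machinery and the *direction* of the
annotation-adjustment effect under controlled inconsistency, not
corpus-level F-scores on shared-task data, which require the external
corpus and distributed parses.

## Problem sizes and determinism

The test suite works at desk scale by design: decoder-optimality checks
use 200 random instances with at most 6 node slots and 4 edges against
exhaustive enumeration; constraint audits run 12 rounds on 80 sentences;
the span-inconsistency recovery experiment trains baseline and Informed
EM for 20 rounds on 300 sentences across 3 seeds with a 100-sentence
held-out set. All randomness flows through explicit seeds; training
itself draws no random numbers, so fits are reproducible bit for bit.

## Known limitations

* The exact decoder is exact for the two validity conditions only; the
  target-side condition is handled by refinement, so the refined
  assignment is not guaranteed to be the constrained optimum (the same
  approximation the refinement idea was introduced for).
* Merged-event expansion emits one GE/PosReg pair per THEME protein of
  the composite node; CAUSE edges attach to the regulation component
  only. Which component should carry CAUSE is not determined by the
  merged-event definition; the regulation reading was chosen for its
  causal semantics.
* Constraint softening or annealing over rounds, and a marginal
  (Inside–Outside-style) E step over all assignments, are out of scope.
* The a2 `M` (modification) lines of Task 2/3, sentence splitting, and
  running parsers are out of scope; sentence boundaries, tokens and
  parses are inputs.
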