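---
title: "Concept-filtered recurrence phenotyping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concept-filtered recurrence phenotyping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recurrex)
```

# The problem and the model

Breast cancer local recurrence — malignancy returning at the original site
after lumpectomy, or in the chest wall after mastectomy — is an important
endpoint for outcomes research but is rarely captured as structured data.
It is, however, described in free-text progress notes. `recurrex` treats
recurrence identification as supervised classification over two channels:

* a **narrative channel**: UMLS concepts extracted from progress-note
  sentences, filtered for negation and uncertainty, gated by a curated
  positive concept set, and expanded into within-sentence power sets; and
* a **utilization channel**: the count of pathology reports filed at least
  120 days after the primary diagnosis, on the reasoning that recurrence
  diagnosis and treatment generate biopsies and excisions, hence reports.

The classifier is a support vector machine over the union of both
channels. The key modeling assumption is that *combinations* of concepts
within one sentence carry meaning that single concepts do not:
"recurrent" alone is compatible with depression or a distant metastasis,
while {history of breast malignancy} together with {recurrent} in one
sentence is strong evidence of the phenotype. Power sets make those
conjunctions explicit as features, at the cost of feature-space growth —
hence the chi-square selection step.

## Sentence processing

Sentences are split on terminal punctuation followed by whitespace and an
uppercase letter (or end of text), with an abbreviation list (`dr`, `pt`,
`no.` …) consulted before the break; text is then lowercased and every
non-alphanumeric run becomes a single space. Normalization is destructive
by design: the downstream dictionary tagger, the cue filter and duplicate
detection all operate on the same canonical alphabet `[a-z0-9 ]`, which
makes whole-pipeline behavior reproducible from the normalized text alone.
Duplicate notes (a common EHR artifact of copy-forward) are detected by
exact equality of normalized text and only the earliest copy is kept.

## Concept mapping

A dictionary tagger maps every whole-word occurrence of a lexicon surface
form to its CUI. Two deliberate contracts:

* **Overlapping spans from different entries are all kept.** A phrase can
  legitimately denote several concepts ("history of recurrent breast
  cancer" maps to a history concept, a personal-history concept, and
  "recurrent"); collapsing overlaps would destroy the power-set signal.
* **Exact-same-span collisions keep the maximum-score CUI**, with ties
  broken by the lexicographically smallest CUI. This reproduces, at span
  granularity, the "retain the mapping with the maximum MMI score" rule of
  MetaMap-style taggers; span granularity is an assumption, since the
  granularity of that rule is not otherwise specified.

The tagger is a stand-in, not a re-implementation, of MetaMap: the
interface (sentence in, mentions out) is the integration point for a real
concept mapper. The packaged lexicon is synthetic and only needs to cover
the packaged fixtures and template pools.

## Context filtering

Negation uses the published NegEx design: pre-triggers negate mentions
beginning within a 6-token window after the trigger, post-triggers negate
mentions ending within 6 tokens before, and scope terminators ("but",
"however") cut the window. The 6-token window is the standard NegEx
choice.

Separately, whole sentences are dropped when any token matches a
negation-cue stem (`no`, `rule out`, `deny`, `unremarkable`) or an
uncertainty-cue stem (`risk`, `concern`, `worry`, `evaluation`). These
eight stems are mandatory defaults; the full default list adds curated
stems of the kind a development corpus yields (`fear`, `recommend`,
`decreas`, `possib`, …) and is fully configurable as YAML.

**Cue matching is stem-aware rather than plain prefixing.** A token
matches a cue word when it equals the cue, when a light suffix-strip
(`ies/ied → y`, then `ing`, `ed`, `es`, `s`) equals the cue, or when the
cue has at least four characters and prefixes the token. Plain prefixing
fails in both directions: the two-character stem `no` would swallow `now`
(dropping genuine findings like "now with newly diagnosed DCIS
recurrence"), while `deny` would never match `denies`. The chosen rule
keeps "concern" matching "concerned" and "deny" matching "denies" without
the short-stem pathology.

Sentence-level dropping runs before NegEx. Because every sentence a NegEx
trigger like "no" appears in is usually also cue-dropped, the order does
not change the retained set; it is fixed for reproducible stage logs. A
sentence that carries a cue *and* a true positive concept is dropped
entirely — recall lost to this is accepted as part of the method.

## Positive concept set

The shipped positive set has 48 CUIs and the development corpus 93 partial
sentences. Both fixtures are *synthetic reconstructions* (the original
supplementary tables cannot be redistributed): they contain every
recurrence-related CUI printed in the published text plus hand-curated
recurrence vocabulary, padded to the documented counts, and are named
`*_synthetic.*` accordingly. Derivation is reproducible:
`derive_positive_set()` tags the partial sentences and subtracts a
declarative exclusion file (the "manual filtering" of function-word CUIs,
externalized as data), and with the packaged lexicon it reproduces the
48-CUI fixture exactly — a property the test suite asserts.

## Features

Power sets use subset sizes 1–3; a sentence with *n* distinct positive
CUIs contributes `C(n,1)+C(n,2)+C(n,3)` binary keys. Feature values are
**binary presence per patient** rather than counts: power sets are
set-valued evidence, and presence semantics is what chi-square selection
assumes. The published description of the three-concept example counts
"nine" features while enumerating seven tuples; `2^3 - 1 = 7`, and the
implementation follows the enumeration and the power-set definition.

A combinatorial guard caps the distinct CUIs expanded per sentence at 10
(configurable), with a warning, keeping pathological sentences from
exploding the key space.

The pathology-count feature is inclusive at exactly 120 days, counts no
pre-diagnosis reports, and is standardized to zero mean and unit variance
on training data before entering the kernel classifier (an RBF kernel
effectively requires commensurate scales; the binary features are left as
0/1).

Baselines: `full_concepts` uses singleton keys for *all* context-filtered
CUIs — no positive gate and no power sets, matching the much larger
feature count reported for that baseline; whether the original baseline
applied negation filtering is unstated, and shared preprocessing is
assumed. `bag_of_words` uses TF-IDF over whole-note tokens with the
standard smoothed formulation `tf * (log((1+n)/(1+df)) + 1)` and
L2-normalized rows, with document frequencies fitted on the training
split.

## Classifier

* Grid: `C ∈ {1, 11, …, 91}`, `gamma ∈ {0.0001, 0.0011, …, 0.0091}`,
  kernels RBF, linear, polynomial, sigmoid (gamma collapsed for linear).
  "1 to 100 with spacing 10" is read arithmetically from the start point;
  endpoints beyond the last full step are not added. The grid is plain
  data and can be overridden.
* Selection: chi-square of each binary column against the label from its
  2×2 contingency (no continuity correction), top `ceil(0.5 N)` kept, ties
  broken by column order. The pathology count is **exempt and always
  retained**: the statistic assumes categorical presence data, and the
  count is the single continuous feature.
* Model selection: stratified 5-fold cross-validation maximizing
  micro-averaged F1 — implemented literally from pooled confusion counts,
  and equal to accuracy in binary single-label classification. Ties prefer
  smaller C, then smaller gamma, then kernel order rbf < linear < poly <
  sigmoid.
* Probabilities: Platt sigmoid `1/(1+exp(A·d+B))` fitted on out-of-fold
  decision values (5 stratified folds) with Platt's smoothed targets,
  minimized by BFGS. The calibration is implemented in-package because it
  must be deterministic under a seed; libsvm's built-in probability
  training shuffles with an unseedable RNG. Labels use `score >= 0.5`
  (boundary inclusive).

## Evaluation

The train/test split is simple random (the reported split prevalences are
visibly non-stratified) with `floor(0.7 n)` training patients — for
n = 701 that gives 490/211, matching the documented cohort sizes; note
`round()` would give 491. AUC is the midrank Mann–Whitney statistic;
undefined (single-class) AUC is reported as `NA` with a warning.
Fold-wise metrics use the grid winner refitted per fold; significance
between the proposed model and each baseline uses a paired t-test across
the shared folds (folds are shared, so pairing is the appropriate
reading of a "Student's t-test" between methods). Cohen's kappa uses
marginal-product chance agreement.

# The synthetic corpus

The generator emulates the statistical structure the pipeline relies on,
at the documented study conditions: 701 patients, 27.53% recurrence
prevalence, and class-conditional qualifying-pathology-report means of
4.55 (recurrent) and 0.92 (non-recurrent). Counts are negative binomial
(`variance = mu + mu²` at the default dispersion of 1) so the spread can
exceed the mean, which a Poisson would understate. Every patient receives
filler sentences; recurrent patients receive one or more positive
recurrence templates (unless a configurable miss-rate draw suppresses
them); and — in both classes — notes carry cue-bearing recurrence
discussion ("discussed the risk of recurrence", "no evidence of …") and
shared breast-cancer-history sentences. The symmetry is deliberate and
realistic: every patient in such a cohort has a primary breast cancer
history and is followed for recurrence, so history vocabulary and
risk-discussion vocabulary carry no label signal. What separates the
classes, by construction, is exactly what the method claims to use: which
concept combinations survive the contextual filter, plus the pathology
channel.

The confound channel models the documented failure mode: a configurable
fraction of non-recurrent patients receive recurrence phrasing whose
ground truth is a distant or contralateral event, drawn from the *same
template distribution* as true positives (progress-note phrasing does not
reveal the site) plus distant-specific sentences, together with
positive-class-like pathology counts. Raising the confound rate therefore
degrades precision at the 0.5 cutoff — the directional behavior the test
suite asserts.

What the generator does **not** emulate: realistic clinical prose and
note length distributions, misspellings, section structure, inter-note
temporal narrative, and lexicon incompleteness (the packaged lexicon
covers the template vocabulary by construction). Passing tests on
synthetic corpora therefore demonstrate that the pipeline's machinery is
correct and that the planted signal is recoverable — not that the
reported real-data operating characteristics transfer to any particular
EHR.

# Numerical choices and problem sizes

Determinism is end-to-end: corpus generation, fold assignment, model
fitting, calibration and reporting are pure functions of the configured
seeds, and the pipeline stamps every artifact with a configuration hash;
rerunning a configuration reproduces `report.json` byte for byte.

The test suite and the acceptance script run the full pipeline on a
700-patient cohort at 28% prevalence with a reduced 2-kernel × 3-C ×
3-gamma grid (values drawn from the full grid), and the generator's
statistical checks use 2000 patients; these sizes were chosen to exercise
the study conditions while keeping a complete run in the order of a
minute or two on one CPU.

# Known limitations

* The dictionary tagger has no word-sense disambiguation beyond the
  span/score rule, and no real MetaMap adapter is shipped.
* Only the negation/uncertainty dimensions of context are modeled — no
  experiencer or hypothetical handling, and no machine-learned negation.
* A cue-bearing sentence containing a genuine positive finding is dropped
  whole; the method accepts this recall loss.
* The positive concept set, lexicon and development sentences are
  synthetic stand-ins at the documented counts, not the original
  supplementary material.
* Class imbalance is handled by nothing beyond the cohort's enrichment;
  there is no class weighting or resampling, and no alternative learners.
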