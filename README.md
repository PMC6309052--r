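# recurrex

Identifying **breast cancer local recurrence** from electronic health
records is usually done by manual chart review: recurrences are rarely
recorded as structured data, but they are described in free-text progress
notes ("She was found to have an ipsilateral breast tumor recurrence").
`recurrex` implements a concept-based phenotyping pipeline that automates
this review for researchers building recurrence cohorts from EHR data, and
ships a synthetic-corpus generator so the entire pipeline can be developed
and tested without protected health information.

## The method

1. **Preprocessing.** Notes are deduplicated (earliest copy kept), split
   into sentences, and normalized to lowercase alphanumerics.
2. **Concept mapping.** A dictionary tagger maps sentence phrases to UMLS
   concept identifiers (CUIs). When several CUIs claim the same span, the
   highest-scoring mapping is kept — the retention rule used by MetaMap's
   MMI ranking. The tagger sits behind a pluggable interface, so a real
   MetaMap/cTAKES adapter can be substituted; the package ships a synthetic
   lexicon covering its own fixtures.
3. **Context filtering.** NegEx-style negation scoping (triggers, a 6-token
   window, scope terminators) drops negated mentions, and whole sentences
   carrying negation cues (*no, rule out, deny, unremarkable*) or
   uncertainty cues (*risk, concern, worry, evaluation*) are removed.
4. **Positive concept gate.** Only CUIs in a curated 48-CUI positive
   concept set — derived from 93 partial sentences of a development corpus
   that indicate local recurrence — are retained.
5. **Power-set features.** Single CUIs are often ambiguous ("recurrent"
   alone does not imply a breast recurrence), so all subsets of sizes 1–3
   of the CUIs co-occurring in one sentence become binary features:
   a sentence tagging {C1997028, C1387407, C2945760} contributes
   C(3,1)+C(3,2)+C(3,3) = 7 features.
6. **Pathology-count feature.** The number of pathology reports filed at
   least 120 days after the primary diagnosis (recurrence work-ups generate
   pathology reports; the feature is standardized before classification).
7. **Classification.** A chi-square test against the label keeps the top
   50% of features; a support vector machine is tuned by stratified 5-fold
   cross-validation over a grid of kernels (RBF, linear, polynomial,
   sigmoid), C in 1–91 (step 10) and gamma in 0.0001–0.0091 (step 0.001),
   selecting the best micro-averaged F1. Probabilities come from Platt
   scaling fitted on out-of-fold decision values; labels use a 0.5 cutoff.

Three baselines mirror the evaluation design: all tagged concepts
(`full_concepts`), the gated concepts without the pathology count
(`filtered_concepts`), and TF-IDF bag of words (`bag_of_words`).

## Worked example

```r
library(recurrex)

# tag the canonical partial sentence with the 3-concept example lexicon
lex <- load_lexicon(system.file("extdata", "example_lexicon.tsv",
                                package = "recurrex"))
m <- tag_sentence("history of recurrent breast cancer", lex)
m[, c("cui", "matched_text")]
#>        cui                       matched_text
#> 1 C1387407        history of recurrent breast
#> 2 C1997028 history of recurrent breast cancer
#> 3 C2945760                          recurrent

sentence_powerset(m$cui)
#> [1] "C1387407"                   "C1997028"
#> [3] "C2945760"                   "C1387407+C1997028"
#> [5] "C1387407+C2945760"          "C1997028+C2945760"
#> [7] "C1387407+C1997028+C2945760"

# simulate a labeled cohort and compare the model with a baseline
corpus <- generate_corpus(generator_config(n_patients = 120,
                                           prevalence = 0.3), seed = 1)$records
report <- run_experiment(corpus, modes = c("proposed", "bag_of_words"),
                         grid = list(kernels = c("rbf", "linear"),
                                     C = c(1, 41), gamma = 0.0011),
                         folds = 3, seed = 2)
cat(render_report_markdown(report), sep = "\n")
```

which prints (three mentions; seven power-set features; and, on this
120-patient simulated cohort):

```
## Cross-validation results

| Method (features) | P (SD) | R (SD) | F (SD) | AUC (SD) |
|---|---|---|---|---|
| proposed (671) | 0.93 (0.12) | 0.78 (0.29) | 0.82 (0.19) | 0.91 (0.09) |
| bag_of_words (271) | 0.76 (0.21) | 0.48 (0.23) | 0.54 (0.16) | 0.86 (0.09) |

## Held-out test results

| Method (features) | P | R | F | AUC |
|---|---|---|---|---|
| proposed (671) | 0.80 | 0.80 | 0.80 | 0.85 |
| bag_of_words (271) | 0.38 | 0.50 | 0.43 | 0.74 |
```

The concept-filtered model dominates the token baseline because the
contextual filter removes the "discussed the risk of recurrence" style
sentences that make raw tokens uninformative, and the pathology-count
feature adds an orthogonal signal. `report$counts` logs how many mentions
each filtering stage dropped.

A thin command-line wrapper is installed at
`system.file("cli", "recurrex", package = "recurrex")` with subcommands
`validate`, `simulate`, `tag`, `derive-positive`, `featurize` and `run`.

## Data provenance

No protected health data is included. The packaged lexicon, positive
concept set (48 CUIs), development partial sentences (93 fragments) and
note templates are synthetic reconstructions — built from concept
identifiers and example sentences printed in the published literature plus
hand-curated recurrence vocabulary — and carry `synthetic` in their file
names.
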