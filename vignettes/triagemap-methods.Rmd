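---
title: "triagemap: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{triagemap: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagemap)
```

# What the package does

Curated protein–protein interaction (PPI) databases record, for each
article, whether it reports interaction data and which experimental
detection methods (PSI-MI methods vocabulary) were used. `triagemap`
supports that curation workflow with two supervised components:

* **Triage** (article classification): binary relevance classification
  of title+abstract records using unigram/bigram indicator features,
  feature selection by mutual information or chi-square score, and
  either multinomial naive Bayes (NBM) or a polynomial-kernel SVM.
* **Ontology mapping** (method assignment): for each (full-text
  article, ontology node) pair, 21 lexical-match features are computed
  against a per-node lexicon (concept name, synonyms, manual keyword);
  tree-based classifiers decide whether the pair is positive, and every
  emitted annotation carries an evidence sentence.

Both components are domain independent: any labeled text corpus works
for triage, and any OBO ontology works for mapping.

# Text normalization

All matching and feature extraction operates on normalized tokens:
lowercase, punctuation (ASCII plus the Unicode punctuation/symbol
categories) replaced by spaces, whitespace tokenization, removal of
purely numeric tokens, then Porter stemming (the original 1980
algorithm, implemented in the package and validated against the
published step examples). Choices worth noting:

* Punctuation becomes a **space**, not the empty string, so
  "two-hybrid" tokenizes as `two`, `hybrid` and matches the
  space-separated method name.
* Numbers are dropped only when a token is entirely digits;
  alphanumerics like `gal4` are kept — they are informative method
  terms.
* Order: numeric tokens are dropped **before** stemming.
* Stemming is *not* idempotent in general: a stem that itself ends in
  a single `s` re-stems (`kinases` → `kinas` → `kina`). Vocabularies
  are therefore always built from a single normalization pass, and the
  recipe version is recorded in models and lexicons; mixing recipe
  versions is a hard error.

Sentence splitting (needed for evidence extraction) is a deterministic
rule: a run of `.!?` followed by whitespace and an uppercase letter or
digit ends a sentence unless the period closes a known abbreviation
(`Fig.`, `et al.`, ...). Offsets into the raw text are preserved
exactly.

# Feature scoring

For a term and a binary document class, a 2×2 table is built from
**document-level presence** (a term occurring seven times in one
document counts once — features are uniformly weighted throughout).
Two scores are computed on every table:

* Mutual information, in **bits** (base 2, recorded in the vocabulary
  metadata since the source material reports scores without a base),
  with the 0·log 0 = 0 convention. For binary variables the value lies
  in [0, 1].
* Pearson chi-square by the closed form
  n(ad − bc)² / ((a+b)(c+d)(a+c)(b+d)), no continuity correction, no
  minimum-count filter. A degenerate margin scores 0 rather than
  erroring, so a term present in every document is simply never
  selected. Margin products are computed in double precision — at a
  few thousand observations they overflow 32-bit integers.

Top-k selection sorts by score descending with ties broken by term
ascending in the C locale, making `select_top_k(v, k1)` a prefix of
`select_top_k(v, k2)` for k1 ≤ k2 and all runs byte-reproducible.

# Triage classifiers

Documents are binary indicator vectors over the selected vocabulary.

**NBM** is the multinomial event model with add-one smoothing over
those indicators. One structural property matters for interpreting
tests: if the selected vocabulary contains no term that occurs in
negative documents, the negative class has zero feature mass, add-one
smoothing makes both class-conditional distributions nearly uniform,
and posteriors collapse toward the class prior — the model cannot
separate even a perfectly separable corpus. This is a property of the
multinomial model, not an implementation artifact; the recovery tests
therefore run NBM with a vocabulary large enough (unigrams, k = 50)
that background terms carry negative-class mass.

**SVM** uses a polynomial kernel (x·y + 1)^d with d = 1 and cost 1 by
default (the unstated defaults of the toolkit the original system
used; both configurable), trained by coordinate descent on the L1-loss
dual with a deterministic sweep order; the kernel's constant term
plays the role of the bias. Decision values are mapped through a
logistic to give graded confidences in [0, 1]; `calibrate = FALSE`
reproduces raw hard 0/1 scores (which rank meaninglessly — the
motivation for calibrating by default). The decision threshold is 0.5
on the calibrated confidence.

Ten named run presets (`act_preset_names()`) encode
algorithm / n-gram orders / feature count / training-composition
combinations. The preset labels do not name a selection score; the
presets default to chi-square, overridable. The
"training+development" vs "development" split tags are corpus
composition presets interpreted by the caller, not hard-coded data.

# Ontology mapping

Each node's lexicon holds its normalized name token sequence, synonym
token sequences, deduplicated unigram/bigram sets for concept and
synonyms separately (a `combined` switch folds concept n-grams into
the synonym sets, since the original grouping is not recoverable), and
the normalized manual keyword.

**Term statistics.** MI and chi-square for every node-derived n-gram
are computed on the training corpus. The class definition for a term
is "document annotated with at least one node whose lexicon contains
the term"; this is a declared choice (the source material does not
state its label) and is recorded in the statistics metadata.

**The 21 pair features**: 2 perfect-match flags (full normalized token
sequence contiguous in the document), 4 term-match flags, 4 match
ratios (matched n-gram types over lexicon n-gram types; 0 for empty
lexicon sets), 4 MI sums and 4 chi-square sums (each **distinct**
matched n-gram counted once), node popularity (training annotation
count), a pluggable regex-annotator hit (0 unless a pattern file is
supplied — the original annotator was external), and keyword presence.

**Feature selection** ranks the 21 features by the chi-square of the
label against a supervised binarization: each feature is split at the
threshold (midpoints of sorted distinct values) that maximizes the 2×2
chi-square. This approximates the toolkit-style selection the original
used; multi-interval MDL discretization is deliberately not
reproduced. Thresholds and the full ranking are stored in the model.

**Learners.** Four tree-based classifiers are provided over the
selected features: a single entropy-split tree (`j48`), bootstrap
bagging with per-node random feature subsets (`random_forest`, 25
trees, mtry = ⌊√p⌋), the same randomized trees without bagging
(`random_committee`), and a depth-limited tree with naive Bayes models
at impure leaves (`nb_tree`). Confidence is the mean leaf probability
across members (Laplace-smoothed class fraction, or the NB posterior);
pairs at confidence ≥ 0.5 become annotations. All randomness flows
from the run seed, so identical configurations are byte-reproducible.
Negative training pairs default to *all* non-gold (document × node)
pairs; a per-document ratio mode with seeded down-sampling exists
because the original construction is unstated.

**Evidence sentences.** Each sentence scores the sum of chi-square
values of the distinct concept-name unigrams it contains; the highest
score wins, ties go to the longest sentence (raw character count —
"longest" is otherwise undefined), then to the earliest offset. Flags
exist for synonym inclusion and per-occurrence summation; both are off
by default.

# Evaluation

Confusion counts are pooled over prediction units (documents for
triage, pairs for mapping: micro averaging) before metrics. All 0/0
conventions give 0, so an empty-prediction system scores 0. MCC is the
standard closed form and satisfies MCC²·n = chi-square of the
confusion table (enforced by a cross-module property test, since the
printed formula is unavailable). AUC iP/R: at each gold item's rank
the raw precision is taken; interpolated precision at recall r is the
maximum raw precision at any recall ≥ r; the area is the mean of the
interpolated precision over the |gold| recall points, and gold items
absent from the ranking contribute 0. This convention is frozen and
documented because the original scoring script's exact convention is
unknowable; note that for a monotonically improving tail of the
ranking, interpolation lifts all earlier recall points (a reversed
perfect ranking scores g/N, not the mean of raw precisions).

# Synthetic fixtures: the stated world

The generators exist so that every stage is testable offline; they
emulate the *shape* of the challenge corpora, not biomedical prose.

* **Triage fixture**: Zipf-distributed background tokens
  (`vocab_size` 120, `doc_length` 40), `n_signal` = 5 planted terms.
  Planting is deterministic (`signal_rate` = 1): each signal term
  appears in every positive, giving it exactly chi-square = n and
  MI = 1 bit at `noise_rate` 0. This is the reading of "planted
  class-discriminative terms" under which the advertised recovery
  properties (signal occupies the top-|signal| ranks under both
  scores; both classifiers reach held-out F1 = 1.0) are attainable;
  with probabilistic planting a positive carrying a single
  low-frequency signal term can be outvoted by absent-term evidence
  and the properties fail for reasons unrelated to correctness.
  `noise_rate` remains the single leakage dial.
* **Mapping fixture**: a generated ontology of two-token method names,
  token-disjoint across nodes and from the background vocabulary;
  per-document gold count 1 + Poisson(mean − 1) with mean 2.2,
  matching the 2.1–2.4 annotations-per-article regime of curated
  interaction corpora; each gold node's name is embedded verbatim in a
  sentence with probability `mention_rate`. At `mention_rate` 1 /
  `distractor_rate` 0 the corpus is perfectly separable by the
  perfect-match feature alone — a green recovery test establishes
  pipeline plumbing and learner sanity, **not** performance on real
  articles, where names are paraphrased, shared across nodes and
  mentioned without being used.

What green tests do *not* establish: headline performance numbers on
the original challenge corpora (external, not desk-available) are out
of scope and no test claims them.

# Numerical and determinism notes

* All sorting tie-breaks are lexicographic in the C locale (radix).
* The SVM dual solver stops at a 1e-6 step tolerance or 300 sweeps.
* Tree impurity gains must exceed 1e-12 to split; naive-Bayes leaves
  floor the per-feature standard deviation at 1e-3.
* Chi-square/MCC arithmetic is double precision throughout.
* Every CLI run logs its config hash and seed; two runs of any preset
  with the same seed produce byte-identical prediction files.

# Known limitations

* Porter stemming is not idempotent for stems ending in `s` (above).
* The multinomial NBM degenerates on vocabularies without
  negative-class mass (above); the SVM does not.
* The ontology hierarchy is deliberately unused (mapping treats nodes
  independently).
* The regex-annotation feature is a hook, constant 0 without a
  supplied pattern file, so models trained without it simply learn to
  ignore the column.
* Evidence-sentence quality is property-tested (score maximality, tie
  rules) only; no reference annotations for evidence exist.
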