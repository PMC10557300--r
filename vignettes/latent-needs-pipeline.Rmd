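---
title: "Mining latent needs from interview transcripts: the method behind latentneeds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining latent needs from interview transcripts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentneeds)
```

## The problem

Transcribed interviews with dementia patients and their caregivers carry
*latent needs*: desires a speaker holds without clear self-awareness, often
signalled by expectation adverbs ("it would be good to have...", "after
all...") rather than stated outright. The classification unit is the
*record* — everything a subject says in answer to one interviewer question.
Two properties of such corpora drive the design of this package:

* **Heavy class imbalance.** Records carrying a latent need are rare
  (on the order of 343 in 7574 for caregivers, 63 in 2073 for patients).
* **Idiosyncratic vocabulary.** Spontaneous speech about personal experience
  produces many one-off expressions. A word used once, by one speaker, in one
  record cannot generalize, yet it inflates the feature space.

The pipeline addresses the second problem with a morpheme-selection statistic
and the first with balanced random undersampling, then asks the practical
question: does the selection step help a standard text classifier?

## The selection statistic

Records are tokenized into morphemes (nouns by default; see *Counting unit*
below) and counted per class: $A$ = records labelled as carrying a latent
need, $B$ = records labelled as not. Within each class the counts are
standardized against that class's own vocabulary:

$$z(x) = \frac{c(x) - \mu}{\sigma},$$

with $\mu$ and $\sigma$ the mean and population standard deviation of the
occurrence counts over all morphemes of the class. The selection score of a
morpheme is the magnitude of the difference of its class Z-scores,

$$\mathrm{score}(x) = \sqrt{\left(z_A(x) - z_B(x)\right)^2}
  = \left| z_A(x) - z_B(x) \right|,$$

computed over the union vocabulary. A morpheme absent from one class is given
that class's Z-score at count zero, $(0 - \mu)/\sigma$, rather than being
dropped: a word used only when needs are being voiced is exactly the kind of
signal the statistic should surface.

Intuitively, a one-off idiosyncratic word has a count close to the bulk of
the distribution in both classes, so its two Z-scores nearly cancel; a word
whose usage differs between the classes relative to each class's spread
scores high.

### The exclusion threshold

Morphemes scoring *less than 25 % of the total* are excluded. The referent of
"the total" is genuinely ambiguous, so all three readings are implemented in
`select_morphemes()` and the choice is explicit:

* `fraction_of_max` (default): exclude below `fraction x max(score)`.
* `quantile`: exclude below the nearest-rank `fraction`-quantile (a
  bottom-quartile cut at 0.25).
* `absolute`: exclude below `fraction` on the raw score scale.

`fraction_of_max` is the default because a plain bottom-quartile cut is
inconsistent with the vocabulary retention observed in practice on real
interview strata (roughly 25–41 % of nouns kept), while a maximum-relative
rule naturally produces heavy exclusion on heavy-tailed count data. On such
data the maximum score is large, so the default can retain only a few percent
of the vocabulary; the retained set is dominated by the genuinely
discriminative words, which is the intent. Ties at the threshold are kept —
exclusion is strictly "less than". Exclusion is monotone in `fraction` for
the two relative strategies, and `kept`/`excluded` always partition the union
vocabulary; both properties are asserted in the test suite.

### Degenerate classes

If every count in a class is identical, $\sigma = 0$ and the Z-score is
undefined. One degenerate class yields all-zero Z-scores with a warning —
selection is then driven entirely by the other class. Two degenerate classes
are an error: no discriminative signal is computable.

## From morphemes to features

**Counting unit.** Downstream vectorization operates on nouns, so the default
counting unit is nouns (first part-of-speech field 名詞); `all_morphemes` is
available since the statistic itself is defined for any morpheme. The
morpheme key is the dictionary (base) form when the analyzer provides one,
else the surface form, after NFC normalization — this pools inflectional
variants into one count.

**Tokenization** is pluggable. The MeCab adapter handles real Japanese text;
the fixture tokenizer consumes pre-tagged `surface/POS[/base]` text and is
what the tests and the synthetic generator use, so the package never depends
on an installed analyzer.

**TF–IDF.** The dialect is a real degree of freedom, so both common forms are
provided. The default `smooth` variant is
$tf \times (\ln\frac{1+N}{1+df} + 1)$ with L2-normalized rows — the de-facto
standard in mainstream machine-learning libraries and therefore the likeliest
match to how such pipelines are usually run; `raw` is the literal
$tf \times \ln\frac{N}{df}$ with no normalization, under which a term present
in every document vanishes. Records with no in-vocabulary tokens become zero
rows (logged, not fatal).

**Balancing and splitting.** All minority-class records are kept and an
equally sized seeded uniform subset of the majority class is drawn without
replacement, giving $2 \times \min(n_{yes}, n_{no})$ records (686 from
343/7231; 126 from 63/2010). The 70/30 split is stratified by label with the
per-class test count $\lceil 0.3 \times n \rceil$; this rounding reproduces
480/206 and 88/38 exactly, which unstratified or floor-rounded splits do not.
The product $(1-0.7) \times n$ is rounded to 9 decimals before the ceiling so
floating-point noise (e.g. $0.3 \times 30 = 9.000000000000002$) cannot
inflate a test fold.

## Fitting scope: pooled vs strict

The workflow order this package reproduces fits morpheme selection and idf on
the **whole labelled corpus** before sampling and splitting. That order leaks
test-fold document frequencies and selection decisions into training — a
deliberate property of the reproduced design, not an oversight — so
`run_pipeline()` exposes it as `mode = "pooled"` (default) alongside
`mode = "strict"`, which fits selection and idf on the training fold only and
transforms the test fold with the training idf. Every report embeds the
resolved configuration including the mode, so the two are never silently
conflated.

## The classifiers

Three standard families are compared, with library-default hyperparameters
(recorded in every report; no tuning is in scope):

* multinomial Naive Bayes with add-one smoothing, treating TF–IDF weights as
  fractional counts (the multinomial rather than Bernoulli variant, the
  common choice on TF–IDF features);
* SVM with linear kernel and cost 1 (the text-classification convention on
  high-dimensional sparse features; RBF available via `hyperparameters`);
* random forest with 100 trees.

All fits and predictions are seeded; random-forest vote ties are broken under
the model seed so a fixed seed gives byte-identical predictions. A trained
model stores a fingerprint of its training vocabulary and refuses matrices
built over a different vocabulary, which catches accidental mixing of the
with/without-selection arms.

Evaluation uses the standard 2x2 confusion matrix with "latent need = yes"
positive, and accuracy, precision, recall, F-measure reported both raw and
rounded to two decimals, half away from zero — the precision and convention
at which such result tables are printed, and the precision at which the test
suite compares against the twelve bundled reference matrices.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces labelled corpora with the statistical structure
the method assumes:

* class imbalance (defaults: 343 needs / 7231 no-needs records, the caregiver
  stratum; the patient stratum 63/2010 is one configuration away);
* a Zipf-like background vocabulary (3000 words, exponent 1.1) shared by the
  classes;
* a small planted discriminative vocabulary (20 words, 15 % of token mass in
  the no-needs class) whose frequency is multiplied by `effect` (default 3)
  in needs records — `planted_truth()` returns it for recovery tests;
* idiosyncratic words (1500) each confined to a single record — the noise the
  selection statistic exists to remove;
* negative-binomial record lengths (mean 30 tokens, dispersion 5), a marker
  adverb embedded in needs records with probability 0.9 so the annotation
  stage is exercisable, and a patient/caregiver role mix of 0.2.

Vocabulary sizes were chosen once to sit at the scale of real interview
strata (thousands of background nouns, of which roughly a third are
single-record words); record length and dispersion are typical of a spoken
answer of a few sentences. Tokens are symbolic (`bg0001/名詞`...): the
generator makes no attempt at Japanese grammar, discourse structure,
annotator noise, or correlation between discriminative words. Passing tests
therefore demonstrate that the implementation is correct and that the method
recovers planted signal under its own assumptions — not that comparable
F-measures would be reached on real transcripts, where the discriminative
signal is weaker and not multinomially clean.

The test and validation suites run the generator at reduced sizes chosen to
keep each property informative: recovery of planted words uses 200 records
per class with a 500/20/300 vocabulary at effect 3 (the regime where at least
half the planted words should reach the top score decile); end-to-end
classification checks use 200–800 records with proportionally smaller
vocabularies; null-calibration uses 20 seeds at 80 records per class. These
sizes are the package's validation conditions, stated here so they can be
scaled up by anyone wanting tighter Monte Carlo error.

Because $|z_A - z_B|$ grows with a word's frequency even when the classes do
not differ (count noise scales with the count), the null-effect calibration
test compares planted words against frequency-matched background words rather
than the background at large.

## Seeds and reproducibility

One top-level seed drives everything: undersampling uses `seed + 1`, the
split `seed + 2`, and the k-th model family `seed + 10 + k`. Two runs with
the same configuration are identical, and the resolved configuration (with
the seed) is embedded in every report and run manifest.

## Known limitations

* The marker lexicon matches raw substrings; いい in particular is a common
  string, so marker flags are candidate indicators only — training always
  uses the human `label` field, never `marker_flag`.
* Whether real runs matched markers before or after morphological analysis,
  and whether counts used surface or base forms, is not knowable from the
  reproduced design; substring matching and base-form keys are this package's
  documented defaults, exposed as options.
* Sample sizes in the patient stratum (38 test records) make the reported
  metrics coarse: one record moves F by about 0.02, which is why comparisons
  are made on 2-dp rounded values.
* No cross-validation, calibration, n-grams, or embedding features; the scope
  is the selection statistic and the three-classifier comparison around it.
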