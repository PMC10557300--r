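# latentneeds

Patients and caregivers voice *latent needs* — desires they hold without
clear self-awareness — in transcribed interviews, and policy makers would
like to find those passages automatically. This package implements a complete,
reproducible pipeline for that task on Japanese interview transcripts: it
flags candidate records with a lexicon of expectation adverbs (あるといい,
いい, やっぱり, やっぱ, やはり), selects class-discriminative morphemes by a
per-class Z-score difference statistic, vectorizes records with TF–IDF,
balances the heavily skewed classes by random undersampling, and compares
multinomial Naive Bayes, a linear-kernel SVM, and a random forest — each
with and without the morpheme-selection step — via confusion-matrix metrics.

It is aimed at health-services text-mining researchers who have (or plan to
obtain) interview transcripts with human latent-need labels, and at anyone who
wants to study the selection statistic itself: a synthetic corpus generator
with planted discriminative vocabulary makes every stage testable without
access-restricted interview data.

## The selection statistic

Interview speech is full of idiosyncratic, one-off expressions that are poor
predictors at population scale. To strip them, occurrence counts are
standardized per class. For morpheme *x* with count *c(x)* in one class,

    z(x) = (c(x) − μ) / σ

where μ and σ are the mean and (population) standard deviation of counts over
that class's vocabulary. With *A* the records labelled as carrying a latent
need and *B* the rest, each morpheme in the union vocabulary is scored

    score(x) = √( (z_A(x) − z_B(x))² ) = | z_A(x) − z_B(x) |

(a morpheme absent from one class takes that class's z-score at count 0).
Morphemes scoring below a threshold — by default 25 % of the maximum score;
nearest-rank quantile and absolute-scale rules are available — are excluded
before TF–IDF vectorization. Classifiers are then trained on a
class-balanced random undersample with a stratified 70/30 train/test split,
and evaluated by accuracy, precision, recall and F-measure with
"latent need = yes" as the positive class.

## Worked example

```r
library(latentneeds)

cfg <- synth_config(n_yes = 150, n_no = 600, vocab_background = 300,
                    vocab_discriminative = 12, vocab_idiosyncratic = 150,
                    effect = 3, seed = 20)
co  <- generate_corpus(cfg)
res <- run_pipeline(co, pipeline_config(seed = 8))
res$counts[c("sampled", "train", "test", "vocab_full", "vocab_kept")]
#> $sampled    [1] 300
#> $train      [1] 210
#> $test       [1] 90
#> $vocab_full [1] 462
#> $vocab_kept [1] 14
as.data.frame(res$metrics)
#>   role        family condition accuracy precision recall f_measure TN FP FN TP
#> 1  all   naive_bayes    with_z     0.78      0.82   0.71      0.76 38  7 13 32
#> 2  all           svm    with_z     0.81      0.87   0.73      0.80 40  5 12 33
#> 3  all random_forest    with_z     0.80      0.83   0.76      0.79 38  7 11 34
#> 4  all   naive_bayes without_z     0.74      0.69   0.89      0.78 27 18  5 40
#> 5  all           svm without_z     0.84      0.92   0.76      0.83 42  3 11 34
#> 6  all random_forest without_z     0.82      0.85   0.78      0.81 39  6 10 35
```

Reading the output: the 750 labelled records were balanced down to 300
(150 per class), split 210/90, and the selection step cut the 462-noun
vocabulary to 14 morphemes — on this corpus the planted discriminative words
plus the strongest background words. Each row is one classifier in one
condition on the 90 held-out records; `with_z` rows used the selected
vocabulary, `without_z` rows the full one. All six runs sit well above the
0.67 F-measure of an always-positive baseline on a balanced test set, and
`res$report` tabulates the same numbers side by side with the higher-F
condition marked per model family.

A command-line front end with `synth` / `annotate` / `select` / `vectorize` /
`run` / `evaluate` subcommands is installed at
`system.file("cli", "latentneeds.R", package = "latentneeds")`.

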