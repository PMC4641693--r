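# mirlocate

Locates the mature miRNA within a plant pre-miRNA hairpin.

Finding hairpin-shaped precursors is the easy half of miRNA annotation;
the hard half is saying *where* in the hairpin the ~21-nt mature miRNA
sits — an error of a few nucleotides changes the seed and therefore every
downstream target prediction. `mirlocate` is for researchers who have
candidate or validated pre-miRNA sequences (e.g. from a hairpin discovery
tool or a miRNA registry) and need nucleotide-resolution placement of the
mature strand, plus the machinery to train and evaluate such a locator on
their own annotated data.

## Method

For a precursor of length *n* folded into its secondary structure, every
interval of 16–30 nt is a candidate mature miRNA. Each candidate's
miRNA:miRNA\* duplex is derived from the pair table (star strand traced
through the outermost pairs, 2-nt 3' overhang) and encoded as a fixed
440-feature vector: 197 sequence properties (length, mono-/di-nucleotide
frequencies, one-hot nucleotide context around the duplex strand ends),
30 structural properties (pair counts, bulges, internal loops, windowed
pairing averages, perfect-run statistics, distances to the terminal loop
and stem base, duplex energy), 22 positional entropies H(i) of the
base-pair probability distribution around the guide ends, and 191
sequence–structure combination counts. A classifier — random forest by
default; SVM, naive Bayes, kNN and decision tree are available — is
trained on annotated duplexes against length-matched pseudo-miRNA
segments sampled from the same precursors at a chosen positive:negative
ratio (RPNS, default 1:5). At test time each candidate (p, L) receives a
score and the mature miRNA is placed by the summed-score rule

    S(p) = Σ (16 ≤ L ≤ 30) score(p, L),
    p_pred = argmax_p S(p),   L_pred = argmax_L score(p_pred, L),

with the passenger strand reported alongside. Accuracy is summarized as
the cumulative fraction of predicted starts/ends within d nucleotides of
the truth (d = 0..10). Folding uses ViennaRNA's `RNAfold` (with partition
function for the entropy features) when available, with a bundled
maximum-pairing fallback for environments without it.

## Worked example

Simulate an annotated corpus of hairpins with planted guides, train,
cross-validate, and locate mature miRNAs in held-out hairpins:

```r
library(mirlocate)

corpus <- simulate_corpus(60, seed = 42)       # synthetic annotated hairpins
pres   <- fold(corpus$sequences)               # RNAfold (or maxpair fallback)
ds     <- build_training_set(pres, corpus$annotations, rpns = 5, seed = 42)
ds
#> <mirna_dataset> 360 samples (60 positive, 300 negative), RPNS 1:5

crossval(ds, k = 5, algorithm = "rf", seed = 42)
#> <cv_report> 5-fold rf: mean AUC 0.981 (folds 0.99 0.99 1.00 0.95 0.97)

model <- train(ds, "rf", seed = 42)
held  <- simulate_corpus(10, seed = 777, id_prefix = "held")
preds <- predict_corpus(fold(held$sequences), model)
preds[1, c("premirna_id", "start", "end", "arm", "score", "summed_score")]
#>   premirna_id start end arm score summed_score
#> 1    held0001    54  74  3p 0.746        8.562

evaluate_resolution(preds, held$annotations)[c(1, 6), ]
#>   d start_freq end_freq
#> 1 0        0.5      0.3
#> 6 5        0.9      0.9
```

Row one of `preds` says: in `held0001` the mature miRNA is predicted at
positions 54–74 on the 3' arm; `score` is the classifier probability of
the winning candidate and `summed_score` the S(p) mass at its start. The
resolution table says 50% of held-out starts were placed exactly and 90%
within 5 nt. `gini_importance(model)` ranks which of the 440 features the
forest used; on this corpus the duplex position anchors (`dist2Helix`,
`dist2Loop`), guide composition (`MNC_U`) and the entropy at the guide
start lead.

A command-line wrapper with `simulate`, `featurize`, `train`, `predict`
and `evaluate` subcommands is installed at
`system.file("cli", "mirlocate", package = "mirlocate")`; it is a thin
shell over the functions above (FASTA in, TSV/JSON out, exit codes
0/2/3/4 for ok/usage/data/engine errors).

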