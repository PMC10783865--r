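# tcrbinder

Transfer learning for TCR–pMHC binding prediction in R.

Whether a T cell receptor (TCR) recognizes a peptide presented by an MHC
class I molecule is the gating event of adaptive immunity and of TCR-based
immunotherapy, yet labeled TCR–pMHC pairs are scarce while unlabeled
repertoire and presentation data are abundant. `tcrbinder` implements the
BERT-style transfer-learning approach to this problem for researchers who
want a fully inspectable, scale-configurable reference implementation:

* **TCR encoder** — a transformer over CDR3β sequences (default 4 layers,
  256 dimensions, 8 heads) pretrained by masked language modelling (MLM).
* **pMHC encoder** — a segment-aware transformer over
  `[start, 34-residue MHC pseudo-sequence, 8–15-residue epitope]` inputs,
  pretrained jointly on selective masking (binder records only) and a
  binding-score regression head; binding affinities enter on the unit scale
  `1 − log(IC50)/log(50000)`.
* **Prediction head** — with both encoders frozen, rank-1 mapping layers
  flatten each embedding matrix per row and per column; the concatenated
  vectors feed a 200–100–50 ReLU MLP (dropout 0.4) with a tanh output,
  trained Siamese-style with the contrastive margin loss
  `ReLU(1 + f⁻ − f⁺) + 0.2(f⁻² + f⁺²)` against per-epoch resampled
  negatives from a healthy repertoire.
* **Percentile-rank scoring** — a candidate's raw score is ranked against
  the same pMHC paired with 1000 background TCRs (midrank ties).
* **Benchmarking** — zero-shot (epitope-disjoint) split construction,
  AUC-ROC (Mann–Whitney), AUC-PR (average precision), PPV@k, Youden
  cutoffs, and resampled 1:100 negative evaluations.
* **Interpretability** — received-attention residue profiles, motif vs
  non-motif attention contrasts (paired Wilcoxon across clusters), and
  attention–distance correlations with permutation p-values from PDB-derived
  residue geometry.
* **Synthetic data** — seeded generators for every input with planted,
  recoverable ground truth (conserved motifs, per-allele anchor rules,
  a TCR↔epitope k-mer compatibility rule, toy interface geometry), so the
  whole pipeline is testable end to end on one CPU.

The transformer core (forward pass and analytic backpropagation for both
training heads) is written in RcppArmadillo and verified against finite
differences in the test suite.

## Worked example

A scaled-down but complete study — pretrain both encoders on synthetic
data with planted rules, train the frozen-encoder prediction head, and
evaluate zero-shot on epitopes never seen in training:

```r
library(tcrbinder)

st <- run_planted_study(seed = 1, verbose = TRUE)
str(st$metrics)
#> List of 6
#>  $ presentation_auc : num 0.859
#>  $ zero_shot_auc_roc: num 0.852
#>  $ zero_shot_auc_pr : num 0.833
#>  $ youden_threshold : num -0.346
#>  $ youden_j         : num 0.606
#>  $ bayes_auc_bound  : num 0.906
```

`presentation_auc` is the held-out AUC of the pMHC encoder's regression
head on planted anchor rules; `zero_shot_auc_roc/pr` measure pair
prediction on epitope-disjoint test pairs. Both approach the
`bayes_auc_bound` (the best any model can do at the generator's 10% label
noise), showing the planted recognition rule is recovered. The numbers
above were produced by the command shown, with seed 1.

Scoring and ranking a single candidate pair (the first held-out positive):

```r
pool <- gen_background_tcrs(2000, seed = 7)
str(rank_score(st$binder, st$tcr_enc, st$pmhc_enc,
               cdr3b = st$pairs$test$cdr3b[1],
               epitope = st$pairs$test$epitope[1],
               pseudo = st$pairs$test$pseudo[1],
               pool = pool, n = 1000, seed = 8))
#> List of 3
#>  $ rank: num 0.913
#>  $ f   : num 0.329
#>  $ n   : int 1000
```

The candidate's raw score beats 91% of a 1000-strong healthy background
ensemble paired with the same pMHC.

A command-line front end wraps the same functions
(`exec/tcrbinder synth | pretrain-tcr | pretrain-pmhc | train-binder |
rank | evaluate`); small synthetic example tables live in `inst/extdata/`.

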