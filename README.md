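# ProtFuse

ProtFuse prioritises candidate disease genes from protein sequence alone.
It is aimed at computational biologists who have a curated set of
disease-associated proteins (compiled, say, from GWAS/ClinVar-style
databases), a pool of background proteins, and per-protein numeric
embeddings from a protein language model — and who want a reproducible,
fully testable classification pipeline around them: corpus curation,
embedding management, a hybrid neural classifier, cross-validated
evaluation, architecture ablations, and sequence-perturbation robustness
experiments.

## The model

Each protein is represented by one fixed-length embedding vector
(dimension `num_feature`). The classifier runs two branches in parallel:

* a **Transformer encoder** (multi-head scaled dot-product self-attention;
  per head `A = softmax(QKᵀ/√d_k)`, `O = AV`, with `d_k = d_model/n_head`,
  heads concatenated and projected back to `d_model`), stacked over
  `n_encoder_layers` pre-norm layers, and
* a **CNN** that reshapes the embedding to a zero-padded square grid
  (`side = ⌈√num_feature⌉`), applies a valid 2-D convolution with ReLU
  (`Y[o,i,j] = max(0, Σ W[o,c,p,q]·X[c,i+p,j+q] + b_o)`) and
  non-overlapping max pooling.

The two branch features `T` and `C` are combined by a learned
**attention fusion** module,

```
a = softmax(W₂ tanh(W₁[T;C] + b₁) + b₂),   a_t + a_c = 1 per sample
F = [a_t·W_t·T ; a_c·W_c·C]
```

followed by a fully connected softmax head. Ablation variants (plain
concatenation, CNN-only, Transformer-only) are one config field away.
Training (cross-entropy, Adam, early stopping) and the analytic backward
pass of every layer are implemented in base R and verified against
loop-written equation oracles and finite-difference gradients in the test
suite.

Evaluation follows the standard protocol: stratified k-fold
cross-validation reporting accuracy, precision, recall, F1, MCC, AUC and
AUPR (with ROC/PR curve points per fold), plus confusion-count primitives.
Curation utilities include cleaning of non-canonical residues, a
CD-HIT-style greedy redundancy filter (k-mer identity, default threshold
0.9), and seeded negative sampling disjoint from the positive set. A
synthetic corpus generator with planted motifs, near-duplicates and a
deterministic embedder makes the whole pipeline testable offline.

## A worked example

```r
library(ProtFuse)

# a balanced synthetic corpus: 100 positives carrying a 10-residue motif,
# 100 matched negatives
gen <- generateCorpus(generatorSpec(nPerClass = 100, seed = 1))

# deterministic embeddings, 64 dims, strong class separation
emb <- embedSynthetic(gen$corpus, numFeature = 64, classShift = 0.5,
                      noiseSd = 0.1, seed = 2)

cfg <- modelConfig(dModel = 64, nHead = 4, nEncoderLayers = 2, seed = 3)
report <- crossValidate(emb, labels(gen$corpus), cfg, k = 5, seed = 4)
round(aggregateMetrics(report), 3)
#> accuracy precision    recall        f1       mcc       auc      aupr
#>    0.950     0.953     0.950     0.950     0.903     0.981     0.980
```

The aggregate row is the arithmetic mean over the five held-out folds.
With the package's study-scale corpus (500 sequences per class, as used
by `scripts/acceptance.R`) the full model reaches a mean AUC above 0.999.

The report carries per-fold metrics (`foldMetrics()`) and ROC/PR curve
points (`foldCurves()`); `serializeFoldReport()` writes JSON plus curve
TSVs. `runAblationGrid()` compares architecture variants on one shared
fold split; `truncateSequences()`, `shuffleSegment()` and
`runNoiseSweep()` drive the incomplete-sequence and shuffle-noise
robustness experiments. A thin command-line front end lives at
`inst/scripts/protfuse`.

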