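---
title: "Predicting antibody deamidation hot spots from sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting antibody deamidation hot spots from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deamidr)
```

## The problem

Asparagine (N) and glutamine (Q) side-chain amides hydrolyse spontaneously
to acidic residues. In a therapeutic antibody this *deamidation* can erode
potency and stability, so developability screening tries to find the liable
sites — "hot spots" — as early as possible, ideally from sequence alone.

The experimental ground truth comes from forced degradation: antibodies are
stressed (elevated temperature and pH for up to eight weeks), digested, and
measured by peptide mapping, yielding a percent-deamidation value per site
per time point. `deamidr` implements the downstream computational workflow:

1. **Labeling.** A site is a hot spot when its measured deamidation extent
   rose by strictly more than 1.0 percentage point over either early stress
   step (week 0 to 1, or week 1 to 2). Sites without measurable deamidation,
   and sites lost from the peptide map, are inactive. The resulting datasets
   are heavily imbalanced (roughly one active site in eight).
2. **Features.** Each candidate site is described two ways: a *global*
   per-residue contextual embedding of the full chain from a protein
   language model (pLM), and a *local* fixed-width sequence window centred
   on the site, tokenised and encoded by a learned embedding plus a
   bidirectional LSTM.
3. **Models.** Three variants share one architecture family: `global_only`
   (site vector → two hidden layers with dropout → head), `local_only`
   (window encoder → head), and `chimeric` (both feature blocks
   concatenated → fully connected head). The classification head emits one
   probability; swapping it for a three-neuron linear head turns the same
   network into a regressor for the extents at 2, 4 and 8 weeks.
4. **Evaluation.** Because a predict-all-inactive classifier already gets
   ~88% accuracy on an 276/2009 composition, evaluation leans on
   imbalance-aware statistics: precision, recall, specificity, F1, the
   Matthews correlation coefficient (MCC) and ROC/AUC, under stratified
   k-fold cross-validation.

## Embedding backends

The production global encoder is a pLM such as the 650M-parameter ESM-2,
whose per-residue hidden states have d = 1280. No deep-learning runtime is
available (or desirable) in this package's test environment, so the backend
is pluggable:

* `make_custom_embedder(fn, d, name)` wraps any function mapping a sequence
  to an n × d matrix — for example hidden states exported from an external
  ESM-2 run.
* `make_mock_embedder(d, seed)` is a deterministic test double. Every
  (offset, residue) pair within ±2 of a position gets a fixed seeded basis
  vector, and the residue's embedding is the sum of the five basis vectors
  selected by its neighborhood. This keeps the two properties the pipeline
  relies on — determinism across processes and context sensitivity — while
  remaining *informative*: the embedding is linear in the one-hot encoded
  neighborhood, so downstream models can generalise across folds. A flat
  hash of the 5-mer would be deterministic too, but fold-to-fold
  generalisation would then hinge on accidental 5-mer collisions, which is
  not what a contextual embedder is a stand-in for.

Rows of the embedding matrix align 1:1 with sequence positions; boundary
handling uses a dedicated out-of-chain symbol, and backends declare a
maximum context length (exceeding it is an explicit capacity error, never a
silent truncation).

## The local encoder and the window summary

Windows are always odd-width (default 31, the plateau of the window-size
sweep; sweepable 3–61), centred on the site, PAD-filled beyond chain
termini, and never cross chain boundaries. PAD has a trainable embedding;
`X` (unknown residue) is its own token.

The bidirectional LSTM leaves one genuinely open design choice: how to
summarise the per-step hidden states into one window vector. We initially
used the final state of each direction — the minimal reading of the
architecture diagram — but at desk scale this fails for wide windows: with
w = 31 the training signal reaching any single step is so diluted that the
model never leaves the all-negative regime (MCC 0) before early stopping
fires. Mean-pooling the hidden states over steps fixes this without
changing parameter counts, and is what the package uses. This is a
deliberate deviation recorded here: final-state summaries are fine for
short windows but are not trainable at w = 31 under this package's CPU
budgets.

## Training protocol

All variants train with Adam on binary cross-entropy (classification) or
masked mean-squared error on the measured extents rescaled to [0, 1]
(regression; absent targets are masked out). Regularisation is dropout
after each head layer plus early stopping: a stratified validation split
(10% of the training portion) is carved out, and training stops once the
validation objective has failed to improve for more than `patience`
consecutive epochs, restoring the best epoch's weights. Every stochastic
ingredient — initialisation, shuffling, dropout, fold assignment — draws
from R's RNG under the configured seed, so (data, config, seed) →
bit-identical models.

Two configuration profiles exist:

* `run_config()` — the package defaults (token dim 16, LSTM hidden 64 per
  direction, head 256 → 64, dropout 0.3, lr 1e-3, batch 64, patience 10).
* `benchmark_config()` — the desk-scale profile used by this package's own
  tests and acceptance benchmarks: token dim 8, LSTM hidden 16, head
  64 → 32, mock embedder d = 32, lr 5e-3, patience 20. These sizes were
  chosen so a full three-variant, five-fold cross-validation finishes in
  minutes on one CPU; they are a runtime compromise, not a claim about the
  best attainable accuracy.

The loss accepts an optional positive-class weight (`pos_weight`). The
default is 1 (no re-weighting). Small local-only models on heavily
imbalanced synthetic worlds sit in a regime where probabilities never cross
0.5 although the ranking (AUC) is good; the planted-rule recovery
experiments therefore set `pos_weight = 4`. The main benchmark does not.

Decision thresholding is strict: a site is called active iff its
probability exceeds the configured threshold (default 0.5); regression
outputs are clamped to [0, 100] percent.

## The synthetic world

The real training corpus for this kind of model — dozens of antibodies with
per-site stress time courses — is proprietary wherever it exists, so the
package ships a generator that emulates its statistical structure:

* **Chains.** 45 molecules by default, each a heavy (330–450 aa) and light
  (110–230 aa) chain drawn i.i.d. from an antibody-like composition with
  N and Q at ~4% each.
* **Kinetics.** Each N/Q site gets a first-order rate constant
  `k = base(X+1 dipeptide) × mult(X−1 residue) × exp(σ·z(neighborhood))`,
  and a noiseless extent `D(t) = Dmax (1 − e^{−kt})` with Dmax = 80%.
  Base rates follow the canonical liability ordering NG ≫ NS ≈ NN > other
  N ≫ Q; X−1 multipliers favour S, E and W precedents; `z` is a fixed
  seeded linear function of the residues within ±5 of the site
  (σ = 0.6 by default). The constants were calibrated once so the default
  dataset lands at ≈12% measured actives (seed 7 realises 0.112) and were
  then frozen.
* **Measurement.** Gaussian noise (sd 0.3 percentage points), clamping to
  [0, 100], censoring below the 0.1% limit of quantitation (reported as 0,
  matching how undetected deamidation enters the inactive class), and a 2%
  chance per site of losing peptide-map coverage entirely.

What a green benchmark establishes — and what it does not: the synthetic
world is sequence-local by construction, with no structure, solvent
accessibility, pH/temperature dependence, or inter-site correlation, and
its noise is homoscedastic. Passing the recovery benchmarks demonstrates
that the pipeline can learn a planted sequence-local rule through the full
feature/training/evaluation stack; it says nothing about accuracy on real
antibodies, which the published numbers address with proprietary data.

Because labels derive from noisy measurements of a continuous quantity
crossing a threshold, sites whose true early increment is near 1.0% carry
irreducible label noise; this keeps desk-scale MCCs in the 0.5–0.7 range
by design rather than saturating at 1.

## Numerical and convention choices

* Metrics with zero denominators are reported as 0 (not NaN) so fold
  aggregation stays total; aggregate dispersion is the sample (n−1) sd.
* AUC uses the tie-aware rank (Mann–Whitney) formulation — exact and
  directly checkable against pair counting.
* Stratified folds canonically order sites by (molecule, chain, position)
  before the seeded shuffle, making fold membership independent of row
  order; within each class, members are dealt to the currently smallest
  folds so fold sizes stay within one site of each other.
* The labeling rule treats absent extents as 0 when differencing; an
  uncovered site is always inactive but keeps `covered = FALSE` so reports
  can distinguish "measured inactive" from "never measured".
* Motif probing isolates one slot: probe windows are all-PAD except the
  center N and the probed X+1/X−1 residue, so the score reflects that
  slot's marginal effect under the trained local model.
* The motif baseline is Asn-specific: Q sites and chain-terminal N are
  never flagged by NG/NS/NN rules.

## Known limitations

* The BiLSTM window summary is mean-pooled; attention or max-pooling were
  not explored.
* Heavy and light chains are embedded independently; any paired-chain
  context a real pLM could exploit is out of reach of the mock backend
  anyway.
* The regression head is trained separately from the classifier (shared
  architecture, separate runs), not multi-task.
* `window_sweep` re-trains from scratch per size; no warm-starting.
* The CLI's per-chain screening aggregate (sum of predicted extents over
  predicted hot spots) is one reasonable reduction; other summaries (max,
  CDR-weighted) may suit specific triage questions better.
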