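# coxfuse

Multimodal survival prediction in R: modality-specific neural encoders, a
margin-based cross-modal similarity loss with random in-batch pairing,
attention-weighted modality fusion, and a non-linear Cox hazard head — with
preprocessing, a censored concordance index, PCA visualization of learned
representations, and a synthetic multi-omics generator so the whole
pipeline runs and is tested without any external download.

## The problem and the model

Cancer cohorts give you, per patient, a clinical table (cancer type,
gender, race, histological type, age), several numeric omics matrices
(mRNA, miRNA, copy number), and right-censored survival labels (time
$T_i$, event indicator $E_i$). `coxfuse` trains one network over all of
these *modalities*:

1. **Encoders.** Each modality is encoded to a fixed-length vector
   $\alpha_j \in \mathbb{R}^m$ ($m = 128$ by default): fully connected
   layers with batch norm and ReLU for omics; categorical embeddings with
   dropout plus batch-normalized age for the clinical table. Stacked
   columns give a per-patient representation matrix
   $A \in \mathbb{R}^{m\times n}$.
2. **Cross-modal similarity loss.** With
   $\mathrm{sim}(x,y)=\sum_i \cos(\alpha_i(x),\alpha_i(y))$ and
   $\mathrm{sim}(x,x)=\sum_{i<j}\cos(\alpha_i(x),\alpha_j(x))$, matched
   random patient pairs contribute
   $L(x,y)=\max\{0,\,M+\mathrm{sim}(x,y)-\tfrac12\mathrm{sim}(x,x)-\tfrac12\mathrm{sim}(y,y)\}$
   (margin $M=0.2$). A batch of size $B$ contributes $\lfloor B/2\rfloor$
   pair terms, not all $\binom{B}{2}$.
3. **Attention fusion.** $s_j=\tanh(W_j\alpha_j)$, row-wise softmax across
   modalities yields weights $P$, and $c_i=\sum_j p_{ij}a_{ij}$ fuses $A$
   into one vector per patient. Missing modalities are masked out of the
   softmax.
4. **Hazard head.** A two-hidden-layer ReLU network maps $c$ to a scalar
   log-risk $h(x)$, trained with the averaged negative Cox partial
   log-likelihood $L_{sur}$; the full objective is
   $L = L_{sur} + \lambda L_{sim}$ with $\lambda = 0.3$.

Evaluation uses the censored concordance index (C-index): the fraction of
comparable patient pairs ($T_i > T_j$, $E_j = 1$) whose risk ordering
matches ($h(x_i) < h(x_j)$).

## Worked example

```r
library(coxfuse)

fx <- make_fixture("default")     # 600 synthetic patients,
ds <- fx$data                     # clinical + mRNA + miRNA, 30% censoring
ds
#> Multimodal survival dataset
#>   600 patients, 408 events (32.0% censored)
#>   clinical: 4 categorical + 1 continuous variable
#>   mRNA: 240 features, 4.7% missing-modality patients
#>   miRNA: 100 features, 5.2% missing-modality patients

fit <- coxfuse(ds, synthetic_config(seed = 1L))
summary(fit)
#> Multimodal neural Cox model (coxfuse)
#>   modalities: clinical, mRNA, miRNA
#>   representation length m = 128, fusion = attention, lambda = 0.3, margin = 0.2
#>   trained 23 epochs (best validation C-index 0.747 at epoch 15)
#>   train C-index 0.8560  (360 patients, 51390 comparable pairs)
#>   val   C-index 0.7468  (120 patients, 5702 comparable pairs)
#>   test  C-index 0.8091  (120 patients, 5888 comparable pairs)
```

The held-out C-index of 0.81 sits within 0.04 of the oracle — the C-index
of the *true* simulated log-hazard on the same test patients:

```r
idx <- fit$split$test
c_index(fx$truth$risk[idx], ds$survival$time[idx], ds$survival$event[idx])
#> C-index 0.8392  (4941 concordant of 5888 comparable pairs)
```

so the encoders, fusion and hazard head recover nearly all of the planted
signal. Risk scores for new patients, fused vectors, per-modality
representations and attention weights all come from `predict(fit, newdata,
type = ...)`; `plot(fit)` shows the training curves and
`plot_representations(fit)` the PCA view of the per-modality
representation clouds. `evaluate_cv()` runs the 5-fold protocol,
`modality_sweep()` compares modality combinations, and `ablation_grid()`
runs the three architecture variants (combined, uniform fusion,
similarity loss removed).

A command-line wrapper with `simulate`, `fit`, `predict`, `evaluate`,
`visualize` and `experiment` subcommands is installed at
`system.file("cli", "coxfuse.R", package = "coxfuse")`; datasets are plain
TSV/CSV matrices keyed by a patient-ID column (see `read_dataset()`).

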