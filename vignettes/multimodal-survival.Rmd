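---
title: "Multimodal survival prediction: model, losses and design choices"
author: "coxfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal survival prediction: model, losses and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cancer cohorts such as TCGA provide, per patient, a small clinical table
(cancer type, gender, race, histological type, age), several
high-dimensional molecular matrices (mRNA expression, miRNA expression,
gene-level copy number), and right-censored follow-up: an observed time
$T_i$ and an event indicator $E_i$ (1 = death observed, 0 = censored).
`coxfuse` fits one model across all of these *modalities* to produce a
single per-patient risk score, for researchers who want multi-omics
survival models that degrade gracefully when some patients lack some
modalities.

## Model

**Encoders.** Each modality is mapped to a fixed-length representation
vector $\alpha_j \in \mathbb{R}^m$ (default $m = 128$). Omics encoders are
2–4 fully connected layers, each followed by batch normalization and ReLU.
The clinical encoder embeds the four categorical variables (one embedding
table each, dropout on the concatenation), batch-normalizes age, and
projects the concatenation through one fully connected layer. Stacking the
$n$ modality vectors gives the per-patient representation matrix
$A \in \mathbb{R}^{m \times n}$.

**Cross-modal similarity loss.** An unsupervised, Siamese-style hinge loss
shapes the representation space. With
$\mathrm{sim}(x,y) = \sum_i \cos(\alpha_i(x), \alpha_i(y))$ (same modality,
two patients) and
$\mathrm{sim}(x,x) = \sum_{i<j} \cos(\alpha_i(x), \alpha_j(x))$ (two
modalities, one patient),

$$L(x,y) = \max\{0,\; M + \mathrm{sim}(x,y) - \tfrac{1}{2}\mathrm{sim}(x,x)
- \tfrac{1}{2}\mathrm{sim}(y,y)\},$$

with margin $M = 0.2$ by default. Patients in a batch are matched into
random disjoint pairs and $L_{sim}$ sums $L$ over the matched pairs only —
$\lfloor B/2 \rfloor$ terms instead of the $\binom{B}{2}$ of an all-pairs
contrastive loss, which is the point of the pairing strategy (the all-pairs
variant exists in the test suite as an oracle, not as a training option).

**Attention fusion.** A learned tensor $W \in \mathbb{R}^{n \times m
\times m}$ produces score vectors $s_j = \tanh(W_j \alpha_j)$; the softmax
across modalities of each feature row yields a row-stochastic attention
matrix $P \in \mathbb{R}^{m \times n}$, and the fused vector is
$c_i = \sum_j p_{ij} a_{ij}$ — a per-feature convex combination of the
modalities.

**Hazard head and objective.** The fused vector feeds a two-hidden-layer
ReLU network ending in one node, the log-risk $h(x)$. Training minimizes
the averaged negative Cox partial log-likelihood

$$L_{sur} = -\frac{1}{N}\sum_{i : E_i = 1}\Big(h(x_i) -
\log\!\!\sum_{j : T_j \ge T_i}\!\! e^{h(x_j)}\Big),$$

plus the similarity term: $L = L_{sur} + \lambda L_{sim}$ with
$\lambda = 0.3$ by default. Risk sets are inclusive ($T_j \ge T_i$), i.e.
the naive Breslow-style treatment of ties, exactly as the formula is
written; no Efron correction is applied. Evaluation uses the concordance
index: the fraction of ordered pairs with $T_i > T_j$, $E_j = 1$ whose
predicted risks satisfy $h(x_i) < h(x_j)$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 128 | representation length per modality |
| `margin` ($M$) | 0.2 | hinge offset; larger pulls a patient's modalities tighter together |
| `lambda` ($\lambda$) | 0.3 | weight of $L_{sim}$ in the objective; 0 disables it |
| `fusion` | attention | `uniform` forces even weights (the all-ones-score variant) |
| `variance_thresholds` | mRNA 7, CNV 0.2 | pre-scaling feature filter on raw-value variance |
| `split` | 0.6/0.2/0.2 | train/validation/test fractions |
| `lr`, `batch_size` | 1e-3, 128 | Adam step size and minibatch size |
| `epochs`, `patience` | 100, 10 | cap and early-stopping patience on validation C-index |

Embedding dimensions default to `min(32, ceiling(vocab/2))` per categorical
column and hidden sizes scale with the input width; both are configurable
per modality. The optimizer (Adam), learning rate, batch size and epoch
budget are this package's choices — the training schedule is not part of
the method's definition — and all live in `coxfuse_config()`.

## Preprocessing and missing modalities

Variance filtering happens **before** min-max scaling, on raw values, with
a strict `>` threshold; ties at the threshold are dropped. The default
filter scope is the full cohort (matching how such feature counts are
usually reported); `variance_scope = "train"` restricts it to training
patients and is what we recommend when leakage matters. Min-max scalers and
categorical vocabularies are always fitted on the training split only;
unseen categories at prediction time map to a reserved unknown embedding
row, and out-of-range continuous values are clipped to $[0,1]$.

A missing modality is stored both as an all-zero feature row (the
train-time imputation convention) and as a 0 in an explicit availability
mask. The mask is authoritative: zero-imputed rows are excluded from
variance computation and scaler fitting, the encoders are not run on them
(the representation column is exactly zero), the similarity sums skip them
(the cosine of a zero vector is undefined), and by default they are masked
out of the attention softmax so the remaining modalities renormalize. An
unmasked mode (`mask_missing = FALSE`) is available for strict parity with
implementations that let zero columns compete for weight. Every patient
retains the clinical modality, so at least one column is always available.

## The synthetic generator

`simulate_multiomics()` draws one latent risk factor $z_i \sim N(0,1)$ per
patient plus nuisance factors. Each omics modality is lognormal:
informative features (30% by default) load on $z$ with amplitude
$\sqrt{\text{signal share}}$, all features load on a nuisance factor and
carry Gaussian noise (sd 0.5 by default), and per-feature scales are drawn
log-uniformly so feature variances are heterogeneous and the variance
filter has non-trivial behavior. The clinical table carries its share
through age and the cancer-type category. The true log-hazard is
$1.5\,z$; event times are exponential with rate
$0.02\,e^{1.5 z}$ (proportional hazards by construction, the assumption
the Cox loss makes), censoring is independent uniform with its upper bound
root-solved so the realized censoring fraction hits the target (default
30%) within $\pm 0.05$, and per-patient missing modalities are Bernoulli.
The slope 1.5 makes the latent signal strongly prognostic (oracle
concordance around 0.84), comparable to a pan-cancer setting where cancer
type alone is highly informative; shares 0.3/0.5/0.2 across
clinical/mRNA/miRNA make the multimodal-versus-unimodal comparison
meaningful.

What the generator does **not** emulate: count distributions, batch
effects, feature–feature correlation structure beyond the shared factors,
or informative censoring. Passing tests on it therefore demonstrates that
the machinery works end to end and recovers planted signal — not that any
particular concordance is attainable on real cohorts.

The bundled presets fix these choices: `default` (600 patients,
clinical + mRNA + miRNA, shares 0.3/0.5/0.2, 30% censoring), `tiny`
(20 patients, all four modalities, every single-modality-missing pattern
present) and `null` (`risk_coef = 0`, so any model's expected concordance
is 0.5).

## Numerical choices

* Cosine similarities use exact zero-norm detection (availability flags),
  never an epsilon in the denominator.
* The attention softmax subtracts the row maximum; since scores are tanh
  outputs this is belt-and-braces, but it keeps `attention_weights()` safe
  for arbitrary finite scores.
* The Cox loss exponentiates shifted scores (`h - max(h)`); shift
  invariance is asserted to 1e-8 in the tests.
* Batch normalization uses biased batch statistics with running-average
  (momentum 0.9) estimates for evaluation mode, epsilon 1e-5.
* The pairing permutation is drawn from its own seeded stream
  (`pairing_seed`), re-randomized every batch; an odd leftover patient is
  unpaired and contributes nothing that batch.
* Risk ties in `c_index()` count 1/2 by default (Harrell); `ties =
  "strict"` reproduces the literal strict-inequality definition, which
  scores ties 0. Which convention published concordances use is often
  unstated, so both are exposed.
* All layer gradients are hand-derived base-R matrix algebra and are
  verified against central finite differences (unit level and through the
  assembled objective) in the test suite.

## Design decisions taken where the design was open

* **Sum, not mean, over matched pairs** in $L_{sim}$, as the loss is
  defined; a `pair_reduction = "mean"` flag exists because the summed loss
  scales with batch size, which matters when tuning $\lambda$.
* **Pairs are re-drawn every batch** rather than fixed per epoch; "matched
  randomly in pairs" is otherwise underdetermined, and re-drawing gives
  every patient many partners over training.
* **Batch-wise risk sets** for the Cox loss (the standard for neural Cox
  training); with the default batch of 128 the risk sets are large enough
  to be stable. Validation losses use the full validation set.
* **No normalization of the similarity terms by modality count**: the
  cross-patient sum has $n$ terms and the within-patient sum
  $n(n-1)/2$. For $n = 4$ the hinge is structurally loose at collapse
  ($M + 4 - 6 < 0$); we note this asymmetry rather than "fixing" it, since
  it is part of the loss as defined.
* **`coef()`, `residuals()` and `simulate()` methods are not provided**: a
  neural hazard has no interpretable coefficient vector, and without a
  baseline-hazard estimate (out of scope — the model predicts relative
  risk only) martingale residuals and outcome simulation are undefined.
  `predict()` exposes risk, fused vectors, representations and attention
  weights instead.

## Problem sizes used in the bundled experiments

The shipped benchmark trains on the 600-patient `default` preset
(360/120/120 split). One fit takes a few seconds; the modality sweep (four
combinations) and the ablation grid (three variants) each use five seeds
with fresh splits per seed. These sizes were chosen so that the full
pipeline — including the five-seed sweeps — runs comfortably on a single
CPU while leaving the comparisons well outside Monte-Carlo noise.

## Known limitations

* Training is CPU-bound base R; it is sized for hundreds to a few thousand
  patients and a few thousand post-filter features, not for raw
  20k-feature matrices with large batches.
* The variance thresholds that reproduce published TCGA feature counts
  depend on the (unstated) transform of the raw data; on this package's
  synthetic scale, much smaller cutoffs are appropriate
  (`synthetic_config()` uses 0.05).
* Minibatch Cox risk sets are an approximation to full-cohort risk sets;
  for small datasets pass `batch_size >= n` to make them exact.
* The concordance implementation is the exhaustive $O(n^2)$ pair count —
  exact and fine for thousands of patients, but not the $O(n \log n)$
  algorithm large cohorts would want.
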