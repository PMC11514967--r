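---
title: "Dissecting differential TF binding from sequence: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting differential TF binding from sequence: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Two ChIP-seq experiments targeting the same transcription factor — in two
cell types, under two treatments, or for two paralogous factors — usually
disagree on a large fraction of their peaks, even though both peak sets
carry the same canonical motif. `motifcontrast` asks what *sequence*
features distinguish the sites bound in one condition from those bound in
the other, and answers with a single interpretable classifier.

Peaks present in both experiments (within a configurable matching window,
default 1000 bp) are removed first: shared sites cannot inform the
difference, and their removal is summarised by the Jaccard distance
`1 - |A ∩ B| / |A ∪ B|` over merged matched peaks. Each remaining peak
contributes one 1-kb sequence centred on the best hit of the target-motif
PWM within 500 bp of the summit (the *anchor*); peaks without a hit above a
FIMO-style threshold (p ≤ 1e-4 under the background, computed exactly by
dynamic programming on discretised weights) are dropped and counted. The
larger class is then randomly down-sampled so both classes have equal size.

Three feature channels describe each aligned sequence *s*:

* **Discriminative motif, DM(s).** The aligned core sites (default plus 4
  flanking bp per side) are one-hot encoded and a logistic regression with
  an L1 penalty is fitted to separate the two site sets. The coefficient
  matrix is itself a PWM; because the penalised likelihood is convex, it is
  the best possible PWM for this aligned-site problem, which a
  grid-refinement oracle verifies on tiny instances in the test suite.
  Unlike PWMs derived from probability matrices via log-ratios, its columns
  are unconstrained (a column may carry a single nonzero weight), and the
  LASSO zeroes uninformative cells, which we quantify by the Gini
  coefficient of the absolute weights (0 = all equal, towards 1 = a single
  informative cell; scale-invariant).
* **Nucleotidic environment, NE_i(s).** The sequence (core masked with N's)
  is split into 7 near-equal bins; a region is any run of consecutive bins
  (28 candidates). For each 2-mer the region whose k-mer frequency best
  separates the classes — folded AUROC `max(a, 1-a)`, so enrichment in
  either class counts — is found exhaustively, then the k-mer is extended
  one nucleotide at a time (8 candidates per step, region re-optimised,
  up to 4-mers) and an extension is kept when it gains at least `min_gain`
  (default 0.01) folded AUROC.
* **Co-factors, CF_j(s).** For every PWM of a motif library, each masked
  sequence is reduced to its best both-strand window score per bin
  (13 bins); the best score of any consecutive-bin region follows by a
  bottom-up max over the region lattice (each node is the max of its two
  children — exactness, not approximation, verified against brute force).
  The region with the highest folded AUROC defines the variable.

All discovered variables enter `P(1|s) = sigmoid(a DM + Σ b_i NE_i +
Σ c_j CF_j)`, fitted by `glmnet` with an L1 penalty on the 70% training
split (stratified by class). Feature discovery uses training rows only;
the held-out 30% provides every reported AUROC. Group ablations set one
coefficient group to zero without retraining; the three test-AUROC losses
form the *importance profile*, and K-means over profiles from many paired
experiments (k = 3 by default, 25 restarts; an elbow curve is attached)
summarises the prevailing strategies: co-factor-dominant, core-motif plus
co-factors, or environment plus co-factors.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `window_bp` | 1000 | peak-matching window (bp) for the unique/common partition |
| `halfwidth` | 500 | half sequence length; 1-kb windows centred on the anchor |
| `n_flank` | 4 | flanking bp per side of the core in the DM fit; wider flanks start absorbing environment signal |
| `ne_bins` / `cf_bins` | 7 / 13 | region resolution vs cost; widths differ by ≤1 bp (1000 = 6×143 + 142; 12×77 + 76) |
| `max_k`, `min_gain` | 4, 0.01 | k-mer extension limit and folded-AUROC gain needed to accept an extension |
| `hit_pval` | 1e-4 | per-window tail probability of the anchoring hit threshold |
| `background`, `pseudocount` | uniform, 0.01 | log-odds conversion of probability matrices |
| `train_fraction` | 0.70 | stratified split; all discovery on the training side |
| `n_keep`, `top_n` | 10, 15 | path point for per-variable importance; length of the location report |

## Numerical and design choices

* **Coordinates.** 0-based half-open internally (BED convention); position
  0 of the anchor-relative frame is the sequence midpoint. The anchor is
  the midpoint of the K-bp hit; minus-strand hits are reverse-complemented
  so the core always reads in motif orientation and left/right flank
  regions are comparable across sequences.
* **Window-to-bin assignment** is by window *start* (for k-mers and PWM
  windows alike), so every window is counted exactly once and regional
  counts are exact sums of bin counts; windows near a region boundary may
  extend past it by up to K-1 bp.
* **Ties.** Best-hit ties go to the window closest to the summit, then
  leftmost; region ties to the widest, then leftmost region. Both make
  reruns deterministic.
* **N handling.** Scanning windows containing N score −∞ (never a hit);
  k-mer windows with N leave both numerator and denominator; one-hot rows
  for N are all-zero, contributing nothing to the DM score.
* **λ selection.** The DM fit uses the 10-fold CV deviance minimum. The
  global model uses the conservative `lambda.1se`: discovered features are
  optimised on the same training rows the CV folds are drawn from, so CV
  sees optimistically biased features and the 1-SE rule is the sensible
  guard (see the leakage discussion below).
* **Degenerate inputs.** Constant feature columns are dropped with a
  warning; a model whose every coefficient is ablated scores constantly and
  is reported at AUROC 0.5; all-zero PWMs have no Gini coefficient (error).
* **Intercepts** are fitted but excluded from exported PWMs (they do not
  affect ranking, hence no AUROC).
* **Location report ranking.** Per-variable importance is defined at the
  path point with ~10 nonzero coefficients; the top-15 location report
  ranks by the same ablation measure computed at the path point closest to
  15 nonzeros, so the two reports agree on their common variables.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` plants three independently tunable signals over a
0-order uniform background: per-class nucleotide distributions at chosen
core positions; multiplicative regional k-mer enrichment (implemented by
planting or disrupting occurrences so the expected regional frequency is
multiplied by the stated factor — an exponential-tilt rejection sampler has
vanishing acceptance over hundreds of windows, so planting is the practical
construction; the realised ratio is verified in the tests); and a co-factor
site drawn from its PPM at a uniform position within a region, with
class-specific probability. The core motif sits within ±50 bp of the
nominal summit so anchoring does real work, and 2% of loci carry no core
motif, mirroring the few-percent discard rate of real peak sets. A toy
two-chromosome genome and BED files are emitted so the file-based path is
exercised end to end.

The reference conditions (1000 sequences/class; core position A at 0.8 vs
0.2; ACA ×1.4 over [−150, 500); an 11-bp co-factor at 0.85 vs 0.15 in
[−250, 0)) were chosen so each channel is individually informative
(single-channel AUROC ≈ 0.75–0.85) while the combined model stays off the
AUROC ceiling (~0.93) — the regime where ablation analysis is informative;
with saturating signals every ablated model still classifies almost
perfectly and group ablations become unmeasurable. The co-factor is
planted at higher contrast than the core position because regional k-mer
composition partially proxies motif presence, so part of the co-factor
signal is inevitably shared with the environment channel — the same
NE/CF correlation expected in real data.

What the generator does **not** emulate: higher-order background
composition (an optional concern — real genomes are far from 0-order, and
NE features on real data partly reflect CpG/GC structure rather than
TF-specific environment), repeat elements, indirect binding, peak-strength
variation, replicate structure, or co-occurring motif grammars. Passing
tests on this generator show the machinery recovers what was planted under
clean conditions; they do not certify biological findings on real data.

## Leakage, honesty of the AUROCs, and a known property

Discovery (NE regions, CF regions, DM weights, class PPMs) and model
fitting see only the training rows; permuting test-row labels leaves every
fitted parameter byte-identical (audited in the tests via the `split`
argument of `motif_contrast()`). Test AUROCs are therefore unbiased.

One property deserves emphasis: because the NE and CF variables are
*selected* to maximise training-AUROC, the training data contain genuine
in-sample signal even under a null — the internal CV of the global LASSO
then keeps many columns on null data (their coefficients are small and the
held-out AUROC stays at chance, mean ≈ 0.51 over 20 null replicates in the
test suite). Sparsity of the selected model on null inputs should
therefore not be expected from this architecture; the held-out AUROC is
the honest summary, and the test suite asserts the chance-level
calibration. Model sizes in the 10–25 nonzero range on real-scale inputs
are normal.

## Problem sizes used in the validation suite

Unit tests run at small n (tens to hundreds of sequences). The end-to-end
validation uses the reference 1000 sequences/class (three generator
replicates plus one signal-free control), 20 null replicates at 150/class,
the single-position discriminative recovery at 2000/class, and
1000-instance exactness sweeps for the lattice; these sizes keep the whole
suite within a few minutes on one CPU while leaving the statistical
assertions well-powered.

## Known limitations

* Correlated variables: near-identical library PWMs yield near-identical
  columns; the LASSO arbitrates arbitrarily among them, so a reported
  co-factor should be read as a representative of its motif family.
* Composition confounds: NE variables can absorb co-factor signal (and
  vice versa) when a motif is compositionally distinctive.
* The discriminative PWM assumes the anchoring PWM found the right site;
  for indirect binders use `skip_anchoring = TRUE`, which drops the DM
  channel and centres on summits.
* Repeated motif occurrences are summarised by the best score only; copy
  number is not modelled.
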