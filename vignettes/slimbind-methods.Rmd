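---
title: "SLiMBind: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SLiMBind: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the bundled synthetic data can and
cannot tell you about real proteins.

## The problem and the model

Short linear motifs (SLiMs) sit in intrinsically disordered regions and bind
structured peptide-binding domains. Given such a domain *with a bound
peptide* in its structure, the package asks: within a 50-residue disordered
window of a query protein, which residues are the binding ones?

Two independent signals are combined. The first is physical: every
overlapping k-mer fragment (tripeptides by default) of the window is docked
into a search box built around the crystallographic bound peptide, and each
residue inherits the best (most negative, kcal/mol) affinity over the
fragments covering it, normalised per region into [0, 1]. The second is
statistical: a bidirectional recurrent neural network (BRNN) reads the
sequence plus structural tracks and emits a per-residue binding probability.
Docking alone discriminates weakly; its value is as an input channel to the
network.

The BRNN is the classic bidirectional architecture for protein sequence
labelling: a forward chain `h^f_j = N_fwd(i_j, h^f_{j-1})` and a backward
chain `h^b_j = N_bwd(i_j, h^b_{j+1})` of hidden state vectors with zero
boundary states, and a per-position output
`o_j = N_out(i_{j-hw..j+hw}, h^f_j, h^b_j)` over a local window of inputs.
Each of the three update functions is a two-layer feed-forward network.
Per-residue inputs are 26 channels: a 20-way one-hot amino-acid encoding, a
sequence-length channel, helix/strand/coil probabilities, disorder, and the
normalised docking score. Structural channels are expected from external
per-residue predictors (any three-class secondary-structure predictor and
any disorder predictor producing [0, 1] tracks can be plugged in; the
package does not re-implement them).

## Assumptions

* The receptor structure carries a bound peptide chain that marks the
  binding site; the search box is meaningful only because of it.
* Candidate windows are disordered: the strict mean-disorder > 0.5 filter
  (`disorderFilter()`) encodes this.
* Docking scores are comparable only *within* one region/receptor pair,
  which is why normalisation is per region, never global.
* Binding is treated as a property of the region and receptor *class*, not
  of the exact receptor: the method predicts peptide-binding propensity, not
  receptor specificity.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| window length | 50 | residues | candidate region size; shorter proteins are used whole |
| fragment length k | 3 | residues | supported 2–5; tripeptides balance docking cost and signal |
| box padding | 5 | Å per side | margin beyond the peptide bounding box |
| maximum box edge | 30 | Å | clamped with a warning; engine search-space limit |
| aggregation | min | — | best covering fragment per residue; `"mean"` available |
| hidden-chain width | 11 | units | BRNN state size |
| feed-forward hidden | 20 | units | hidden layer of the three update networks |
| input windows | 7/9/11 | residues | the per-fold ensemble members |
| epochs | 10000 | — | full training schedule |
| initial learning rate | 0.01 | — | halved after 50 stagnant epochs |
| folds | 10 | — | cross-validation |
| decision threshold | 0.4 | — | low false-positive operating point for motif calls |

## Numerical and design choices

Several details are not pinned down by the method's public description; the
package fixes them as follows, and exposes most as arguments.

* **Window centring.** The motif centre is `ceiling((start + end) / 2)`; a
  motif centre within the first or last 25 residues triggers the terminal
  rule (first/last 50 residues). Any fixed convention satisfies "motif in
  the centre"; this one makes tests deterministic.
* **Score normalisation.** `v_i = clamp(-s_i, 0, |s_min|) / |s_min|` with
  the upper reference pinned at 0 kcal/mol: the best residue maps to 1,
  non-negative affinities to 0. A track with no negative score is degenerate
  and returns zeros with a warning.
* **Residue aggregation.** Minimum over covering fragments, mirroring
  best-pose selection; ties need no breaking (minimum is well defined).
* **ROC convention.** Positive call at `score >= threshold` (closed), so the
  threshold-1 endpoint includes perfect-confidence calls; thresholds are the
  sorted unique scores with sentinels, giving curves anchored at (0,0) and
  (1,1). The trapezoidal AUC then equals the pairwise Mann–Whitney
  probability with half-credit ties — the suite verifies this exhaustively
  for every score/label configuration up to n = 6 on a tied grid.
* **Residue pooling.** Dataset-level curves pool residues from all regions
  into one vector (one curve per experiment); per-region macro-averaging can
  be built from the per-item predictions if wanted.
* **Activations and sizes.** tanh hidden layers and tanh chain outputs,
  logistic output unit, hidden sizes 11/20; small enough for desk-scale
  full-schedule runs while leaving the channels clearly separable.
* **Loss.** Mean per-residue binary cross-entropy: outputs are interpreted
  as binding probabilities, and predictions near 1 are confident calls.
* **Length channel.** Parent length / 1000 clipped to [0, 1], constant
  across positions.
* **Training.** Full-batch gradient descent; "error" in the halving rule is
  the training loss. The halving counter resets after each halving, and
  epoch 1 establishes the baseline, so a fully stagnant trace halves first
  at epoch patience + 1. Weight initialisation is uniform(−0.1, 0.1) from
  the run seed; identical seed, data and config give bit-identical models.
* **Deployment averaging.** Cross-validation ensembles three window sizes
  per fold; for unseen sequences all fold ensembles are averaged (pass all
  30 models to `runPredict()`), since per-fold models are exchangeable for
  deployment.
* **Degenerate inputs.** Empty structures, missing chains, one-class label
  vectors, gap-ridden fragment sets and out-of-range spans all raise typed
  errors early; stripping the last chain or normalising a non-negative
  track warn instead, because both can legitimately occur mid-pipeline.
* **Failure policy.** A fragment whose docking call fails is retried once
  and then imputed with the region's median score, with a warning — one bad
  fragment must not kill a 48-fragment run.

## The synthetic generator

`syntheticRegions()` / `syntheticCorpus()` emulate the training conditions:
84 regions of 50 residues, each with one contiguous planted binding span of
3–12 residues (the SLiM length range), a smooth disorder track lying in
[0.55, 0.95] (so every region passes the strict disorder filter),
coil-tilted Dirichlet(1, 1, 3) secondary-structure tracks, and uniform
amino-acid composition. The mock engine scores a fragment
`-(4 + effect × labelled-fraction) + N(0, σ²)` with two decoy poses, so the
docking channel carries signal proportional to `effect/σ` (defaults 2 and
0.1).

What this deliberately does **not** emulate: real amino-acid composition or
motif grammar (the sequence channel is pure noise by construction), receptor
geometry and pose physics, correlated errors between disorder and secondary
structure predictors, and any relationship between sequence and docking
score. Passing tests therefore demonstrate that the machinery recovers a
planted docking signal through the full pipeline — not that the method
attains any particular accuracy on real proteins, which depends on corpus
and docking quality.

## Problem sizes used by the test suite

The full schedule (10,000 epochs, three windows per fold) is a desk-scale
but hours-long computation. The suite instead trains at the corpus's stated
conditions (84 × 50, effect 2, σ 0.1) with one window (9) per fold, 250
epochs and initial learning rate 0.2: full-batch gradients of a mean loss
are small, so a shorter schedule needs a proportionally larger step to reach
the same regime the 10,000-epoch/0.01 schedule converges to. Under that
configuration the cross-validated sequence+docking model must exceed AUC 0.9
out of fold and beat the sequence-only model, whose channels carry no signal
by construction (it hovers at chance). Gradient correctness is checked
against a five-point central finite difference (step 1e-3) with the mixed
relative/absolute criterion (relative error floor 1e-6, absolute bound
1e-9): relative error alone is undefined where the true gradient is zero.

## Known limitations

* The docking adapter ships with a deterministic mock; real docking needs an
  external engine binary plus a user-supplied ligand-preparation step
  (k-mer → 3D ligand file). The engine's scoring internals are out of scope.
* Secondary-structure and disorder predictions are inputs, not products;
  the package validates but does not produce them.
* Scores are not comparable across receptors; rankings are within-region.
* The per-fold ensemble assumes regions of broadly similar length; training
  batches group sequences by length, and very heterogeneous corpora will
  train more slowly.
* No GPU path; the trainer is plain R linear algebra, sized for corpora of
  tens-to-hundreds of 50-residue regions.
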