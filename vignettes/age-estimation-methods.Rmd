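---
title: "Age-group classification with LBP, eigenfaces and a GA-evolved network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-group classification with LBP, eigenfaces and a GA-evolved network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceage)
```

## The problem and the model

Facial aging has two visually distinct phases: from birth to early
adulthood the dominant change is craniofacial morphology (the shape of the
face and skull), while from adulthood onward the dominant change is skin
texture — wrinkles, thinning, loss of elasticity. A coarse age estimate can
therefore be framed as classification into eight brackets (0–5, 6–10,
11–20, 21–30, 31–40, 41–50, 51–60, over 60), using features that respond to
both shape and texture.

The pipeline is:

1. **Pre-processing.** Grayscale conversion (BT.601 luma), face crop,
   resize to S×S, histogram equalization. Face detection is a pluggable
   contract — any function returning candidate boxes can be supplied, and
   the largest box is used — with a deterministic fallback (central square
   of side min(H, W)) so the pipeline is self-contained. Equalization is
   applied **after** the resize; the order affects pixel values slightly,
   and equalizing last guarantees the final crop uses the full intensity
   range.

2. **LBP block histograms.** The 8 neighbors of each interior pixel are
   thresholded against the centre, s(x) = 1 iff x > 0, and summed with
   weights 2^i, i = 0 at the top-left neighbor proceeding clockwise. The
   code map is divided into a rows×cols grid of near-equal blocks
   (remainder pixels join the last row/column of blocks) and per-block
   256-bin histograms are concatenated. Keeping histograms per block
   retains coarse spatial layout — which blocks are smooth cheek, which are
   wrinkled forehead, where the face boundary falls — that a global
   histogram would discard.

3. **Eigenface projection.** PCA of the training feature matrix with the
   1/M covariance normalization. When the feature dimension D exceeds the
   sample count M, the eigenvectors are recovered from the M×M Gram matrix
   and mapped back to length D. Components are unit-norm, sign-fixed
   (largest-magnitude entry positive) for reproducibility.

4. **Classifier.** A single hidden-layer perceptron, tanh hidden units and
   linear outputs scored by argmax, one-hot targets over the 8 groups,
   trained by damped second-order backpropagation: Δw = −(JᵀJ + μI)⁻¹Jᵀe.
   An accepted step (training MSE decreased) multiplies μ by μ_dec; a
   rejected step multiplies it by μ_inc = 10 and retries, and training ends
   when the MSE reaches the goal (1e−3), the epoch cap is hit, or μ exceeds
   1e10. When the parameter count exceeds the residual count the update is
   solved in the dual form Jᵀ(JJᵀ + μI)⁻¹e, which is algebraically
   identical and much cheaper for wide networks.

5. **Genetic algorithm.** Chromosomes are (hidden_size ∈ [1, 64],
   learning_rate ∈ [1e−4, 1], μ ∈ [1e−4, 10], μ_dec ∈ [0.01, 0.99]);
   fitness is 1/max(MSE, 1e−12) of the trained candidate. Each generation
   ranks the population, carries one elite unchanged (making the best
   fitness monotone non-decreasing), and refills by single-point crossover
   (cut uniformly between genes, applied with probability Cp) over the top
   half, then per-gene uniform-resampling mutation with probability Mp.
   Study-scale defaults are Ps = 100, Ngen = 25, Mp = 0.1, Cp = 0.5. A
   candidate whose training diverges receives fitness 0 and evolution
   continues.

Data are ordered by a deterministic stratified interleave (each group
spread evenly over the sequence) and split into contiguous blocks, first
80% training, last 20% held out. The interleave exists because a contiguous
block split of a group-sorted directory would otherwise leave whole groups
out of one block.

## Design choices on genuinely open points

* **Trainer.** The configuration sheet names a damped second-order trainer,
  and μ/μ_dec are exactly that trainer's damping controls, so it is the
  default. A classic gradient-descent-with-momentum trainer (`"gdm"`,
  momentum 0.9, step `learning_rate`) is available as a configuration
  alternative and serves as the convergence oracle in the tests.
* **learning_rate gene.** The damped trainer has no learning-rate
  parameter (the step is fully determined by μ), so that gene is inert
  under `"lm"` and drives only `"gdm"`. It is kept as a fourth gene because
  the chromosome definition lists it; a practical consequence is that
  mutation of this gene is neutral under the default trainer.
* **Hidden layers vs neurons.** The evolved gene is the hidden **neuron**
  count of a single hidden layer (bounds [1, 64]); a shallow MLP is the
  standard reading of an auto-tuned "hidden layer" gene.
* **One-hot coding with linear outputs.** Softmax/cross-entropy would be
  the modern choice, but a sum-of-squares objective is what fitness = 1/MSE
  presumes, and linear outputs keep the residual Jacobian exact.
* **LBP threshold.** Strict (ties give bit 0) by default, matching the
  sign-function definition used here; the common ≥ convention is a config
  switch (`lbp_mode = "geq"`). Neighbor order and bit weights are fixed and
  recorded; any fixed order gives an equivalent descriptor up to bit
  permutation.
* **K selection.** The smallest K reaching 95% cumulative eigenvalue mass,
  capped at M−1, overridable. Eigenvalues below 1e−12 of the leading one
  are treated as numerically zero.
* **Selection scheme.** Rank truncation (top half are parents, paired at
  random); roulette selection is available by config. Elitism count is 1.
* **Per-candidate budget.** 50 training epochs during evolution; the final
  best configuration is retrained with the full 200-epoch budget and kept
  only if it improves on the evolution-time fit.

## The synthetic corpus

Real age-labeled face databases are rarely redistributable, so the package
generates a controllable surrogate. Group g images are ellipses (aspect
distinct across the three child groups — the craniofacial phase proxy) on a
dark background, with an oriented sinusoidal wrinkle field inside the face
whose spatial frequency (2–13 cycles/image) and contrast (2–34 intensity
units) increase with group index (the texture phase proxy), plus a linear
illumination gradient in a random direction (amplitude 20) and Gaussian
pixel noise (sd 3). Per-group counts default to (200, 189, 363, 200, 158,
109, 71, 65) — 1355 images preserving the imbalanced composition of a
realistic collection — and scale by `ceiling(factor × counts)`. Every image
is a pure function of (seed, group, index).

What it does **not** emulate: pose, expression, identity, occlusion,
demographic variation, or any photometric property of real skin. Passing
tests on this corpus show the pipeline is correctly assembled and that the
classifier can exploit group-dependent shape and texture statistics; they
say nothing about accuracy on real faces.

## Numerical and reporting conventions

* CCR percentages are rounded half-up to two decimals; a group with no test
  samples reports an undefined (NA) CCR, not zero.
* Argmax ties break toward the lowest group index.
* Histogram equalization returns constant images unchanged (degenerate
  histogram), and the remap is monotone so pixel rank order is preserved.
* All randomness in a fit flows from one seed; corpus generation draws from
  per-image derived seeds and restores the caller's RNG state.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full pipeline at a reduced
scale chosen to exercise every stage in a few minutes: corpus factor 0.1
(138 images), S = 64, LBP grid 4×4, K = 20 eigenface components, GA with
Ps = 6 and Ngen = 3, over three seeds, against a fixed-configuration
baseline network (10 hidden units, μ = 0.001, μ_dec = 0.1) on the same
corpora. K = 20 is fixed there rather than variance-selected so the
network's input width — and hence the comparison between the evolved and
fixed configurations — is identical across seeds. On these runs the
held-out CCR of the evolved network has a median comfortably above the
12.5% chance level, and it matches or beats the fixed baseline in most
seeded runs; the shipped `scripts/acceptance.R` recomputes both medians
and the win count from scratch.

## Known limitations

* Training MSE is the GA's only fitness signal (no validation fold), so at
  study scale the search can prefer wide, overfitting-prone networks; the
  strong margins of the synthetic groups mask this, real data would not.
* The damped trainer builds the full residual Jacobian; it is comfortable
  at the shipped sizes (hundreds of residuals, a few thousand parameters)
  but is not meant for large corpora or deep nets.
* Only PNG rasters are read; point the loader at another source by passing
  image matrices directly.
* Viola–Jones-style face detection is intentionally out of scope; supply
  any detector function, or rely on the centre-crop fallback (adequate for
  the synthetic corpus, where the face is centred by construction).
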