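---
title: "Methods: density-map enhancement with a volumetric GAN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-map enhancement with a volumetric GAN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cryo-EM maps in the 3–6 Å range sit at the borderline where automated
model building starts to fail: helix pitches blur together, strand
separation vanishes, side-chain density is washed out.  `emgan3d`
implements a volumetric super-resolution approach to this problem: a 3D
convolutional generative adversarial network (GAN) is trained on pairs
of (degraded experimental-quality map cube, high-resolution simulated
map cube) so that, at inference time, it rewrites an input map to look
like a map simulated from an atomic model at high resolution.  The
enhanced map is an *intermediate for model building*, not a measurement
— it should never be interpreted as experimental evidence on its own.

## Data model and pipeline

A density map is a 3-D scalar field on a regular grid with a physical
origin and voxel spacing in Å (`density_map`).  The canonical pipeline
is:

1. **Resample** to a uniform 1.0 Å grid by trilinear interpolation
   (`resample_to_unit_grid`).  Points that fall outside the input grid
   evaluate to 0, matching the zero-padding used downstream.  The
   package resamples *before* normalizing; the ordering is not forced
   by the math (trilinear interpolation commutes with the affine
   normalization up to the clamping of negatives) but is fixed and
   documented so cube frames are unambiguous.
2. **Normalize** to [0, 1]: negatives are clamped to 0 first, then
   `(d - min)/(max - min)` is applied over the *whole map* (not per
   cube), so one global affine transform relates stored and normalized
   densities.
3. **Cube extraction** (`extract_cubes`): a sliding cube of 25³ voxels
   (= 25³ Å³ at the enforced spacing) moves with a stride of 4 voxels.
   The map is zero-padded upward so the last cube covers the final
   voxel; along each axis offsets run `0, 4, …` up to the smallest
   multiple of the stride ≥ `N − 25`.  Cubes are ordered
   lexicographically (first axis most significant) for reproducible
   batching.
4. **Pair filtering** (`make_pairs`): a training pair is kept iff
   *neither* the experimental nor the simulated cube is all zeros.
5. **Reconstruction** (`merge_cubes`): modified cubes are re-assembled
   by per-voxel averaging over all covering cubes, then cropped back to
   the original shape.  Extract→merge is exactly the identity, which
   the tests assert to 1e-9.

Whether one should average in the padded frame or drop partial cubes is
not dictated by the method; padding+averaging was chosen because it
preserves all density and keeps the reconstruction linear.

## Simulated target maps

`simulate_map` plays the `pdb2vol` role: each atom contributes an
isotropic Gaussian with **FWHM equal to the nominal resolution**
(σ = R/(2√(2 ln 2)) ≈ R/2.355), truncated at 3σ, summed on a grid
covering the model bounding box plus 5 Å of padding, then min–max
normalized.  The exact kernel convention used by external simulators
varies (some use σ = R/2, some kernel widths defined via Fourier-space
criteria); since every map is min–max normalized before training, the
choice shifts absolute densities but not the structure of the pipeline.
The FWHM convention is the one documented here and is configurable
through `simulation_config`.

The resolution-targeting rule maps an experimental map's resolution to
its simulated target: **1.8 Å for experimental maps in [3.0, 3.5) and
3.0 Å for [3.5, 6.0]** (`target_resolution_for`).  Both printed source
ranges include 3.5 Å, so a deterministic tie-break was required; 3.5 is
assigned to the 3.0 Å branch.  Default atom weights are 1.0 (a
Z-weighted option exists); waters are excluded by default since the
method is trained on protein density.

## Networks

The architecture follows the SRGAN pattern, transplanted to 3-D:

* **Generator** (fully convolutional, stride 1, spatial shape
  preserved): conv(3³, 32) + PReLU → 15 ResNet blocks, each
  `conv(3³,32) → InstanceNorm → PReLU → dropout(0.25) → conv(3³,32) →
  InstanceNorm`, skip-added to the block input → conv(3³, 32) → a 1³
  single-channel projection conv → tanh → rescale `(x+1)/2`.  The final
  1³ projection is an addition this package makes explicit: a 32-channel
  feature map must become one density per voxel, and a minimal linear
  projection before tanh is the smallest change consistent with a
  per-voxel output.  Where exactly PReLU and InstanceNorm sit inside a
  residual block admits variants (pre- vs post-activation); the order
  above is fixed and used consistently.  The instance norms carry
  learnable per-channel affine parameters (γ, β), as the batch norms of
  the SRGAN family do: without an affine scale, the normalization that
  *ends* each residual branch pins the branch to unit variance per
  channel, so a branch can never make a small contribution — it either
  injects O(1) perturbations or nothing.  With γ the branch amplitude
  is learnable, which is what makes the residual design trainable at
  small scale.

  **Initialization.**  The generator is initialized as a working map,
  not white noise: delta kernels carry the density through the in/post
  convolutions, the second norm of every residual block starts with
  γ = 0 so each block begins as the identity (the standard
  zero-init-residual scheme), and the output stage starts as
  `y = g(x − 1/2)` with g = 2.5, the gain that minimizes the L2
  distance of `(tanh(y)+1)/2` from the identity over [0, 1].  The
  rationale is budget, not accuracy: cube cross-correlation is
  affine-invariant, so a passthrough start already carries the input's
  own correlation with the target, and training refines from there.  A
  conventionally random-initialized network first has to re-learn the
  input–output correspondence, which at desk-scale step budgets it
  provably (in our tests) does not finish — training instead collapses
  into predicting the background, a degenerate minimum that the
  overwhelmingly zero target voxels make attractive.
* **Discriminator**: 10 conv layers (3³ kernels), channel count
  starting at 32 and doubling every two layers (32,32,64,…,512), each
  followed by GroupNorm (group size 16, capped at the layer's channel
  count), PReLU and dropout(0.25); stride-2 convolutions on
  even-indexed layers reduce 25³ → 1³; global average pooling feeds a
  2-logit linear head and softmax.  The stride schedule and pooled head
  are design choices: "stride 1 everywhere" is stated for the generator
  only, and *some* spatial reduction is needed to produce a single
  probability.

Losses (per cube): content = mean squared error between the generated
and simulated cube; adversarial = −D(G(Exp)); generator total =
content + 10⁻³ · adversarial; discriminator = (1 − D(Sim)) + D(G(Exp)).
The printed objectives are linear in the probabilities (not the usual
log form); they are implemented literally, with `loss_mode = "log"`
available as the standard alternative.  One source formula prints the
content term as a *sum* over voxels while the prose calls it a *mean
squared error*; the mean is the default (`content_reduction`), the sum
one switch away.  With the mean, λ = 10⁻³ makes the adversarial term a
small regularizer, which matches the stable behaviour observed in
training.

There is no deep-learning framework in this package's dependency
footprint: convolutions are im2col + BLAS kernels in C++ (Rcpp/
RcppArmadillo) and every backward pass (conv, PReLU, InstanceNorm,
GroupNorm, dropout, tanh, softmax head) is hand-written and verified
against central finite differences in the test suite.

## Training

Per batch: one Adam step of the generator against the current
discriminator, then one Adam step of the discriminator on the same
batch's (simulated, generated-detached) cubes — the one-to-one
alternation that is the SRGAN default.  Defaults follow the reference
setup: learning rate 0.001 for both networks (chosen there from a grid
over {0.01, 0.001, 0.005, 0.0001}; `lr_search` reproduces that harness
at desk scale), batch size 16, 100 epochs, Adam β = (0.9, 0.999).
Training/validation splits are **map-level** (`split_by_map`): no cube
from one source map appears on both sides, for any seed.  All
randomness — initialization, shuffling, dropout — flows from the single
seed in `training_config`, so two runs with the same seed produce
bit-identical histories.

## Synthetic fixtures: what they do and do not establish

Real experimental maps cannot ship with the package, so the fixture
generator (`make_fixture_dataset`) builds toy protein-like chains —
helices (1.5 Å rise, 100°/residue, radius 2.3 Å), strands (3.3 Å rise,
alternating lateral offset), self-avoiding coils (3.8 Å steps) — with
1–3 pseudo-sidechain atoms per residue, and emulates the
experimental/simulated pairing as: high = simulation at 2 Å; low =
simulation of the same model at 5 Å plus Gaussian voxel noise
(sd = 0.05 in normalized density units) re-normalized, on the identical
grid.  Defaults (20 structures of 30–80 residues, 5 Å → 2 Å,
noise 0.05) are the package's stated desk-scale world.

The surrogate preserves what the method assumes — same underlying
structure, degraded detail, matched grids — but *not* the character of
real experimental maps: no CTF effects, no solvent or ice background,
no B-factor variation, no map/model misalignment, no ligands.  A green
tiny-scale learning test therefore establishes that the architecture,
losses and optimization *can* learn the intended low→high mapping end
to end; it does not certify performance on EMDB maps.

## Desk-scale test configuration

The acceptance suite trains a reduced model: 3 ResNet blocks,
6 generator channels, a 6-layer/8-base-channel discriminator, batch 8,
150 steps on 400 cube pairs subsampled from the 20-structure fixture
corpus.  Block count and the ≤300-step cap come from the acceptance
contract; channel width, batch size, discriminator depth and the pair
subsample are this package's desk-scale choices, sized so the whole
suite fits a single-CPU budget (a full 15-block/32-channel model is
~30× the compute).  The pass thresholds themselves (held-out CC above
the input's own CC; enhanced map CC above the input map's CC) are
fixed by the acceptance contract and were not adjusted.

## Numerical choices

* Normalization eps in Instance/GroupNorm: 1e-5; Adam eps 1e-8.
* Min–max normalization refuses constant maps (degenerate-map error)
  rather than returning NaNs.
* Pearson correlation refuses constant inputs; cube-level evaluation
  skips (and counts) cubes whose correlation is undefined.
* The about-mean (Pearson) correlation is the default everywhere:
  min–max normalized maps have a positive floor that inflates
  about-zero correlations.  The about-zero form is available
  (`about_mean = FALSE`) for parity with viewer tools.
* RSCC here is "RSCC-like": the reference density is this package's
  own `simulate_map` (not an external program), with a 2.5 Å mask
  radius around each residue's atoms.  Scores are internally consistent
  for before/after comparisons; absolute values are not comparable to
  other packages' RSCC. Residues with empty or constant masks are
  skipped with a warning, not scored 0, to avoid spurious degradation
  statistics.
* Checkpoints are RDS containers carrying the parameter trees, both
  configs, λ, and provenance (epoch, seed, package version).

## Known limitations

* No automatic experimental/simulated map alignment: callers must
  supply maps on a shared frame (the fixture generator does so by
  construction).
* Single-sample processing (no batched conv kernels); adequate at desk
  scale, slow for production-size training.
* Half-maps, FSC-based resolution estimation, mmCIF input,
  nucleic-acid-specific handling and downstream model building are out
  of scope.
* Maps at the resolution extremes of the stated range (≈6 Å) are the
  regime where this family of methods is least reliable; enhanced maps
  should always be validated against the original experimental map.
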