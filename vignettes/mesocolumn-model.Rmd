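---
title: "Contextually guided feature extraction in a model cortical mesocolumn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contextually guided feature extraction in a model cortical mesocolumn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesocol)
```

## The model

`mesocol` simulates a two-stage account of how neocortical columns in primary
visual cortex select the stimulus features their neurons become tuned to.
The guiding idea is that behaviorally useful low-level features are the ones
that are *contextually predictable*: a feature extracted from one patch of
the visual field should correlate with the same feature extracted from
surrounding, non-overlapping patches, because both reflect the same
environmental causes (an extended contour, a texture, a surface).

The processing unit is the **mesocolumn**, a hypothesized group of seven
minicolumns (~150 µm across). Processing proceeds in two stages:

1. **Layer 4 (L4)** performs a nonlinear, RBF-like transform of the afferent
   input. Each of the `N_L4mc` cells (150 at paper scale) computes a leaky
   integrator over 20 Euler steps (`dt` = 1 ms, `tau` = 4 ms) of a drive made
   of a Hebbian afferent sum, untuned feed-forward inhibition scaled by
   `theta` = 0.65, and anti-Hebbian lateral input scaled by `lambda` = 3.
   Afferent weights learn from LGN–L4 response correlations (rate 0.01,
   rectified L1 row normalization); lateral weights learn the *negative* of
   the L4–L4 correlations (rate 0.1), pushing neighbors apart.
2. **Layer 3 (L3)** reads L4 linearly. Each two-compartment pyramidal cell
   has a basal weight vector `u` over the 7-mesocolumn L4 output
   (7 × `N_L4mc` channels, unit L2 norm) and an apical weight vector `v`
   over the canonical-variate responses of 18 surrounding mesocolumns
   (18 × 20 channels, unit L1 norm). Basal and apical updates move toward
   `sgn(rho) * sqrt(|rho|)` of the cross-compartment correlations at rate
   0.01, so each compartment teaches the other.

Between the two stages sits the package's analytical core: **canonical
variates**, directions `b` in the 7 × `N_L4mc`-dimensional L3 state space
whose projections correlate maximally, on average, with the same projection
in the 18 surrounding mesocolumns. With `K_auto` the auto-covariance of the
central flattened afferent vector and `K_cross` the pooled cross-covariance
with the surrounding mesocolumns, the variates solve the generalized
symmetric eigenproblem `K_cross b = lambda K_auto b`, eigenvalues ordered
decreasingly. The front end is a difference-of-Gaussians LGN layer
(`sigma_center` = 0.8833 px, `sigma_surround` = 2.6499 px, support radius
8 px, baseline 0.1) sampled by 91 ON and 91 OFF cells on a unit-spaced
hexagonal lattice.

## Geometry

The modeled field holds 19 macrocolumns (1 central, 6 at radius 9 px, 12 at
radius 18 px), each containing 7 mesocolumns (central + 6 shifted 3 px at
60° steps). Ring members are placed at evenly spaced angles (60° steps for
the 6-ring, 30° for the 12-rings); only the radii are anatomically
constrained, the angular placement is this package's choice. A further
evaluation ring of 12 mesocolumns at radius 21 px (the L3 RF diameter, so
RFs abut but do not overlap) is used exclusively for measuring contextual
correlations on held-out patterns.

## Numerical choices

* **Eq. 16's inhibition term.** The printed form of the L4 drive reads
  "`theta * sum a_j2`", typographically ambiguous between `sum(a)`,
  `sum(a^2)` and `||a||_2`. Following the conic-RBF interpretation the
  default is the Euclidean norm (`inhibition_norm = "l2"`), with both
  literal readings selectable. More consequentially, the learning rule's L1
  row normalization (rows of `w` sum to 1) makes the afferent sum at most
  `max(a)` (≈ 0.3 on encoded natural images) while `theta * ||a||` is ≈ 1.2,
  silencing every cell under *all three* readings — a network that can never
  fire cannot learn. `l4_respond()` therefore applies the afferent weights
  L2-renormalized per row, making the drive
  `||a|| * (cos angle(w, a) - theta)` before rectification: `theta` acts as
  the cosine of a cone half-angle around the cell's RBF center, which is
  precisely the stated functional role of untuned feed-forward inhibition.
  The learning rule itself keeps the printed L1 normalization verbatim.
* **Cross-covariance symmetrization.** The finite-sample `K_cross` is not
  exactly symmetric; it is symmetrized as `(K + K') / 2` before solving,
  and this is recorded in basis metadata.
* **Ridge.** A 1050-dimensional covariance estimated from 5000 samples is
  ill-conditioned, so `ridge = 1e-6 * trace(K_auto) / dim` is added to
  `K_auto` by default. Basis vectors are conjugate with respect to the
  ridged matrix exactly; conjugacy with respect to `K_auto` itself holds to
  O(ridge).
* **Basis sign and orthogonality.** The contextual correlation of a variate
  is invariant under `b -> -b`, so signs are fixed deterministically
  (largest-magnitude coefficient positive). Vectors are `K_auto`-conjugate,
  not Euclidean-orthogonal; the two coincide only when `K_auto` is a
  multiple of the identity.
* **Degenerate inputs.** Zero-variance channels contribute correlation 0 in
  every learning rule; autoscaling floors zero variances with a warning;
  constant images equalize to 0.5 with a warning; windows that do not fit
  inside an image raise an error rather than padding.
* **Tuning statistics.** Orientation tuning curves use the cycle-mean (F0)
  response, which treats phase-sensitive and phase-invariant cells
  uniformly; HWHH is measured from the peak to the half-height crossing by
  linear interpolation, averaging the two sides when both cross. The
  spatial-frequency grid {0.03, 0.05, 0.08, 0.12, 0.18, 0.25} cycles/px is
  a package default (the source work does not state one). "Moving" gratings
  are 16 discrete phase steps spanning one cycle.
* **Texture clustering.** Per-cell responses are autoscaled before PCA, so
  the separation score is invariant to per-cell affine rescaling; the
  silhouette uses Euclidean distance on the first three component scores.

## Design choices where the design was open

* **Variates fed to L3.** The apical pathway uses all 20 extracted variates
  per context mesocolumn (the normalization constant 360 = 18 × 20 in the
  apical learning rule); restricting to the statistically significant 15 is
  available via `context_variates_per_meso`.
* **Weight initialization.** Afferent L4 memories start i.i.d. uniform(0,1)
  (then normalized); lateral weights start at 0; L3 basal rows are random
  unit vectors and apical rows uniform then L1-normalized. Only "random
  initial weights" is stated upstream; these are the simplest choices
  consistent with the normalizations.
* **Moments from the central mesocolumn.** All mesocolumns are assumed
  statistically identical, so `mu` and `K_auto` are estimated from the
  central mesocolumn only and reused for every view.
* **Autoscaling window.** Basal outputs, apical drives, variate responses
  and the feed-forward signal are autoscaled to zero mean and unit variance
  over each update step's own batch (statistics are recomputed per step).
* **Significance counting.** Contextual correlations of fitted variates are
  selection-biased upward on the fitting set, so significance is always
  evaluated on fresh held-out patterns (this is also the evaluation-ring
  protocol); the test is the two-sided Pearson test at `alpha / n_tests`
  (Bonferroni, default 0.05/20).

## The synthetic stimulus battery

Training photographs are emulated at desk scale by a seeded battery of
procedurally generated images, 75% oriented band-pass textures (a global
orientation filter over white noise, 1/f radial falloff, 20° angular SD)
and 25% pink noise (amplitude 1/f), all histogram-equalized exactly like
loaded photographs. The textures plant the one property the model's
contextual machinery needs: statistics (orientation energy) shared between
distant, non-overlapping windows of the same image. What the battery does
*not* emulate: object structure, broad-band scale mixtures, luminance
gradients, occlusion — so a green end-to-end test establishes that the
mechanism works (contextual guidance finds planted long-range structure and
L3 cells tune to it), not that the learned features match cat V1
quantitatively. The quantitative grating statistics (average L4 HWHH ≈ 18°,
80%/20% complex/simple in L3) are properties of training on natural-image
corpora at full scale and are reported by `scripts/acceptance.R` as
desk-scale stand-ins only.

## Convergence behavior

With afferent rate 0.01 the L4 afferent memory relaxes toward the running
correlation pattern with a ~100-step time constant; the per-step change
`|dw|` therefore rises while responses differentiate, peaks near step 100,
and declines thereafter. Over the printed 20-step schedule the trend is
flat; the package's convergence test probes 200 steps. L3 convergence is
fast by comparison (trace correlation with the final state typically
exceeds 0.9 by the halfway step at desk scale).

## Known limitations

* Temporal context, attention, feedback, deep layers, spiking outputs and
  Dale's law are out of scope (static images, continuous signed outputs).
* Mesocolumns are discrete tiles; overlapping "functional" mesocolumn
  fields are not implemented.
* The pipeline is single-threaded; paper-scale schedules (1000 × 5000 L3
  updates on 150-cell mesocolumns) are supported but take hours of CPU.
* PNG input requires the `png` package; TIFF is not supported (no reader in
  the supported dependency set) — use PGM or CSV instead.
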