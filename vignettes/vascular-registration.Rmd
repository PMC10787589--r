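---
title: "Deformable registration of vascular volumes with a coordinate-based neural field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deformable registration of vascular volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(vesselreg)
```

## The problem and the model

Repeated photoacoustic (PA) scans of the same tissue are geometrically
misaligned by repositioning, and differences in illumination change image
intensities between visits. `vesselreg` aligns a *moving* volume $M$ to a
*fixed* volume $F$ by estimating a dense displacement field. The
transformation is

$$\Phi(x) = x + u(x),$$

where $u$ is represented by a small multilayer perceptron with sinusoidal
activations that maps a normalized coordinate $x \in [-1,1]^3$ of the fixed
image to the displacement (in the same normalized units) of the
anatomically corresponding point in the moving image. The network is
optimized per image pair — there is no training set — by minimizing

$$\hat\Phi = \arg\min_\Phi \; L_{data}(M \circ \Phi, F) + \alpha\, L_{reg}(\Phi).$$

$L_{data}$ is one minus the mean patch-wise normalized cross correlation
(NCC) between vessel-enhanced versions of $F$ and $M \circ \Phi$, and
$L_{reg} = \mathrm{mean}\,|\det J_\Phi - 1|$ penalizes local expansion or
shrinkage. NCC is invariant to positive affine intensity changes, which is
what makes the method robust to fluence differences between visits; the
determinant penalty leaves rotations and shears unpenalized but protects
vessel calibre, which carries the biology one wants to preserve.

Because $u$ is a continuous function of the coordinates, its spatial
Jacobian is computed *analytically* (forward-mode through every layer), not
by finite differences; the reverse-mode weight gradients, including the
second-order path through the Jacobian used by the regularizer, are
likewise exact. Both are pinned to finite-difference oracles in the test
suite.

## Vessel enhancement and the coarse-to-fine schedule

The similarity is computed on multiscale Frangi vesselness images. At scale
$\sigma$ the Hessian is computed by Gaussian smoothing followed by exact
central second differences, multiplied by the $\gamma$-normalization factor
$\sigma^2$. The classic bright-tube response

$$V = \left(1 - e^{-R_a^2/2a^2}\right) e^{-R_b^2/2b^2}
      \left(1 - e^{-S^2/2c^2}\right)$$

uses $a = b = 0.5$ and $c$ = half the maximum Hessian Frobenius norm at
that scale ("auto"); the response is forced to zero where either principal
eigenvalue is positive (bright structures on a dark background).

A numerical note: the second-derivative kernels are the discrete difference
stencils composed with the sampled Gaussian, rather than sampled analytic
Gaussian derivatives. The two agree to $O(\sigma^{-2})$; the discrete
choice makes the Hessian match a finite-difference oracle to machine
precision and is exact on quadratic images, which makes correctness
testable without slack.

Optimization is coarse-to-fine: the scale schedule (default
$\sigma = \{12, 9, 5, 3, 2\}$ voxels, 4000 iterations each) starts with
heavily smoothed images in which only major vessels survive — a low-noise,
well-conditioned similarity landscape — and sharpens progressively so fine
vessels are aligned last. Per stage, the modulated vesselness of both
volumes is precomputed once and sampled by trilinear interpolation; the
alternative (re-filtering the warped image each step) is quadratically more
expensive and not what the per-scale similarity requires.

### Adaptive intensity modulation

Light fluence decays with depth, so deep vessels are dim. The package's
modulation (a declared stand-in for the published contrast-modulation
referenced by the imaging literature; the original algorithm is not fully
specified in our sources) equalizes a per-depth gain: in each depth slab
the gain $g(d)$ is a high percentile (default 99%) of the *significant*
vesselness values — those above `signal_floor` (2%) of the global maximum —
smoothed along depth, floored at `epsilon` (0.05, capping the boost at
20×); the output is `clip(v / g(depth), 0, 1)`. The significance floor
matters: estimating the profile from all nonzero values lets the Frangi
halo around vessels (and noise) set the gain, which saturates junk to 1.0
in vessel-free slabs and actively corrupts the similarity term — a failure
mode we observed and test against. The strategy is pluggable
(`modulation_params(strategy = ...)`).

## Sampling mask and patch geometry

Coordinates are sampled where vessels are: a coarse mask is built on the
fixed image by multiscale Frangi filtering ($\sigma = \{2,3,4\}$) and
adaptive thresholding against
$T(x) = t_{deep} + (t_{surface} - t_{deep}) e^{-depth(x)/\tau}$, with
defaults $t_{surface} = 0.5$, $t_{deep} = 0.05$, $\tau = 10$ mm. The decay
keeps dim deep vessels inside the mask. Depth is measured from a flat
entry plane (the index-0 face of the depth axis); a segmented-surface
offset can be supplied instead.

Each epoch samples 200 mask voxels, expands each into a $5^3$ lattice of
side $2.5\,\sigma_c/100$ *normalized units*, evaluates fixed vesselness at
$x$ and moving vesselness at $\Phi(x)$, and takes one Adam step
(learning rate $5 \times 10^{-5}$) on
$(1 - \overline{\mathrm{NCC}}) + \alpha L_{reg}$ with $\alpha = 0.95$. The
regularizer is evaluated on the 200 patch centres (configurable), not on
all 25,000 lattice points — the Jacobian varies slowly compared to the
patch extent, and this keeps the second-order backward pass cheap.

## Desk-scale configuration

`reduced_config()` exists because the defaults above are sized for
clinical-scale grids (hundreds of voxels per axis) and hours of GPU time.
For the 96³ phantoms used in the tests:

* **Schedule** $\sigma = \{6, 4, 2\}$ *millimetres* (15/10/5 voxels at
  0.4 mm), 300 iterations per scale. The coarse-to-fine strategy only has
  a capture range when the coarsest smoothing is comparable to the
  initial misalignment; at full scale the coarsest kernel (~5 mm) faces
  6–11 mm repositioning displacements. Interpreted in voxels the desk
  schedule would be 2.4/1.6/0.8 mm against 8 mm displacements, and we
  measured the NCC landscape to be *flat* around the identity in that
  regime — no gradient method could start. In mm, the measured landscape
  slopes monotonically into the true minimum.
* **Network** 3 hidden layers × 48 units, $\omega = 30$, and 80 patch
  centres. A smooth repositioning-scale field needs little capacity;
  width is the main CPU cost (the transcendental activations dominate the
  runtime). Severe misalignments (tens of mm) get more budget and
  capacity: the full five-scale schedule, 1000 iterations per scale,
  3 × 64 units, 100 centres.
* **Patch side factor 10** rather than 2.5. The patch side is defined in
  normalized units, so its *physical* size scales with the grid: on a
  ~500-voxel-per-axis grid the default factor yields patches of tens of
  voxels, but on 96³ it yields ~14 voxels at $\sigma = 6$ — smaller than a
  typical 20-voxel initial misalignment, and the NCC term then starts with
  no capture range (we verified the loss plateaus at its maximum). Factor
  10 restores the full-scale physical patch extent.
* **Learning rate** 3e-4, tuned for 900 total epochs instead of 20,000
  (the method's own published practice is trial-and-error tuning of these
  parameters), chosen on a pure translation diagnostic: 5e-5 and 1e-4
  underconverge in this budget, while much larger steps let the sine
  network overfit high-frequency warps that raise patch NCC without a
  coherent bulk motion — the network's spectral bias is the method's only
  coherence prior, and it only operates at moderate step sizes.

## The synthetic phantom world

`phantom_spec()` / `make_pair()` emulate the properties of breast PA
volumes that matter to registration: bright tubular trees on a dark noisy
background (tube peak 1, background 0.02, additive Gaussian noise 0.02),
depth attenuation $e^{-depth/30\,\mathrm{mm}}$, 0.4 mm voxels, and smooth
inter-scan deformation. The default tree has five branching levels
(31 segments, 15 branch-point landmarks): patch-wise similarity needs
neighbouring-vessel context to be discriminative, and a near-empty volume
is both unrealistic — breast PA scans are densely vascularized — and an
unrecoverable registration target (with a 15-segment tree we measured
incoherent wrong-neighbour matches at repositioning-scale offsets). Ground-truth deformations are a small rigid
motion plus Gaussian-windowed displacement bumps, rescaled to a target
mean magnitude (8 mm "normal" — the repositioning range reported for
cup-stabilized scans — and 25 mm "severe" for deliberate mispositioning),
with $\det J > 0$ verified on every grid node. Bump widths are kept at
domain scale (15–25 mm normal, 18–28 mm severe): repositioning deforms
tissue smoothly, and a first rougher parameterization (8–15 mm wavelengths
at full amplitude) produced fields no vesselness-based method could
plausibly invert. The moving image is re-rasterized from the warped
centerline tree (subdivided to ~2-voxel pieces), avoiding the
interpolation blur that resampling would add on top of the deformation; a
resampling mode is kept for comparison.

What a green test does **not** establish: the phantoms contain no
reconstruction artifacts (streaks, limited-view loss), no skin signal, no
physiological change between scans, and their vasculature is far sparser
than a real breast's; absolute metric values are not comparable to
clinical reports.

## Numerical choices and degenerate inputs

* Trilinear sampling outside $[-1,1]^3$ returns a constant fill (0 — the
  dark-background convention); those samples carry zero gradient, so
  structure missing from one field of view neither helps nor hurts.
* NCC patches with centred energy below $\varepsilon = 10^{-8}$ in either
  image contribute NCC 0 and zero gradient.
* The normalized mapping is per-axis and node-centred
  (index 0 ↔ −1, index N−1 ↔ +1), exact at grid corners; landmark errors
  are always reported in mm through the voxel spacing, so anisotropic
  normalization cannot distort them. An isotropic variant (one scale for
  all axes, centred on the volume) is available through the `isotropic`
  argument of the coordinate converters.
* The final network layer is initialized at $\pm 10^{-4}$ so optimization
  starts essentially at the identity transform.
* One RNG seed governs initialization and sampling; a run is exactly
  reproducible and checkpoints are byte-identical across reruns.
* An empty vessel mask (no voxel above the threshold map) is an error
  advising lower thresholds, not a silent fallback.

## Known limitations

* Depth is measured from a flat entry plane, not a segmented surface.
* The modulation algorithm is a reasonable reconstruction, not the
  published original.
* Desk-scale budgets (900 epochs) recover repositioning-scale smooth
  fields; fields with energy at wavelengths near the vessel spacing are
  out of reach at any budget for vesselness-based similarity.
* No symmetric/inverse-consistent variant; one directed field per pair.
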