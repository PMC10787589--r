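# vesselreg

Deformable 3D co-registration of longitudinal vascular volumes —
photoacoustic tomography (PAT) breast scans and images like them — using a
coordinate-based neural network as a continuous displacement field.

## The problem

Repeated PAT scans of the same breast are misaligned by repositioning:
vessels move by millimetres to centimetres between visits, illumination
changes shift intensities, and a different supporting cup changes the
field of view. Before any longitudinal comparison (e.g. monitoring therapy
response), the scans must be brought into one coordinate system.

`vesselreg` estimates the transformation `Φ(x) = x + u(x)` mapping fixed-
image coordinates to their anatomical counterparts in the moving image.
The displacement field `u` is a small multilayer perceptron with
sinusoidal activations (`sin(ω·)`, ω = 30), optimized per image pair by

```
Φ̂ = argmin_Φ  (1 − NCC(M∘Φ, F)) + α·mean|det J_Φ − 1|,   α = 0.95
```

where the similarity is patch-wise normalized cross correlation computed
on multiscale Frangi-vesselness filtered, depth-gain-modulated versions of
both volumes, evaluated coarse-to-fine (default scale schedule
σ = {12, 9, 5, 3, 2}, 4000 iterations each). Patch coordinates are sampled
from a vessel mask on the fixed image (Frangi σ = {2, 3, 4} plus a
threshold map decaying exponentially with depth); each of 200 centres is
expanded into a 5×5×5 lattice (25,000 coordinates per epoch) of side
2.5·σ_c/100 normalized units. Spatial Jacobians of the network are
analytic (forward-mode through every layer), so the regularizer needs no
finite differences; Adam (lr 5e−5) optimizes the weights. Evaluation
reports PSNR, global NCC, Dice overlap of vessel masks, and landmark
target registration error (TRE, mm).

No training data are needed — each pair is its own optimization problem.

## Worked example

There is no bundled binary data: the package generates its own
PAT-like phantoms — a branching vessel tree with depth-dependent fluence
attenuation, noise, and a known smooth "repositioning" deformation — so
the whole pipeline is testable end to end.

```r
library(vesselreg)

spec <- phantom_spec(seed = 1)            # 96^3, 0.4 mm voxels
ph   <- rasterize_phantom(generate_vessel_tree(spec), spec)
def  <- generate_deformation(ph$volume, magnitude_target_mm = 8, seed = 2)
pair <- make_pair(ph, def)                # fixed, moving, paired landmarks

fit  <- register(pair$fixed, pair$moving, reduced_config(seed = 1))

before <- evaluate_pair(pair$fixed, pair$moving, NULL,
                        pair$landmarks_fixed, pair$landmarks_moving)
after  <- evaluate_pair(pair$fixed, pair$moving, fit$model,
                        pair$landmarks_fixed, pair$landmarks_moving)
rbind(before, after)[, c("phase", "psnr_db", "ncc", "dsc", "tre_mean_mm")]
```

The numbers this computes (seed as above, a few minutes on one CPU):

```
  phase   psnr_db     ncc    dsc  tre_mean_mm
  before    21.74  -0.007  0.002         7.17
  after     32.12   0.907  0.779         0.66
```

Reading it: before registration the two scans' vessel maps barely overlap
(near-zero NCC/Dice) and corresponding branch points are ~7 mm apart;
after registration the vesselness images align (PSNR/NCC/Dice rise) and
the landmark error drops below two voxels, i.e. the network recovered the
simulated repositioning. `tidy(fit)` returns the
per-iteration loss history, `glance(fit)` a one-row summary.

`reduced_config()` is the desk-scale configuration used throughout the
tests (96³ grids, one CPU); `registration_config()` holds the full-scale
defaults quoted above. The vignette explains every deviation between the
two.

## Command line

A thin Rscript wrapper over the same functions ships in `exec/vesselreg`
(installed under `system.file("exec", package = "vesselreg")`; put it on
your PATH or call it by full path):

```sh
vesselreg simulate --out sim/
vesselreg register --fixed sim/fixed.nii --moving sim/moving.nii \
                   --config cfg.yaml --out run/
vesselreg evaluate --fixed sim/fixed.nii --moving sim/moving.nii \
                   --model run/model.rds --landmarks-fixed sim/landmarks_fixed.csv \
                   --landmarks-moving sim/landmarks_moving.csv --out run/
vesselreg overlay  --fixed sim/fixed.nii --moving run/warped.nii --out mip.png
```

`overlay` writes the standard two-colour check: blue = fixed MIP,
red = moving MIP, magenta = aligned structure.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's main result from scratch: it generates a fresh
96³ phantom pair with a ground-truth 8 mm mean deformation (seeded from
`--seed`), co-registers it with `reduced_config()`, prints the four
metrics before and after co-registration, and writes the JSON report to
`--out`.
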