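---
title: "Methods: synthetic-CT-assisted deformable registration on digital phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic-CT-assisted deformable registration on digital phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`sctdir` studies one question: does translating a low-quality cone-beam CT
(CBCT) into a CT-quality synthetic image (sCT) before intensity-based
deformable registration improve contour propagation? The package contains
the four ingredients needed to ask it reproducibly on a desk: a contrastive
generative translator, a diffeomorphic demons registration engine,
overlap/surface evaluation metrics, and a phantom generator that plays the
role of the patient cohort. Everything below is computed by the test suite
or the shipped examples; no empirical claim in this vignette goes beyond
what those runs measure.

## Translation model

The translator is a one-way ResNet-style generator `G = G_dec ∘ G_enc`
operating on single-channel 2D slices normalized from a configurable HU
window to `[-1, 1]`. Content preservation is enforced contrastively rather
than with cycle consistency: for each of `L = 4` tap layers (the raw input
plus three encoder stages) and `S = 64` random spatial locations, the
projected feature of the *output* at a location is the query, the feature
of the *input* at the same location is the positive, and the other `S − 1`
locations of the same layer are internal negatives. Each feature passes
through a two-layer MLP head (width `K = 256`) and is normalized to the
unit sphere; the `(N+1)`-way cross-entropy uses temperature `τ = 0.07`.
The total objective adds the adversarial value function (probability
convention) and weighs both contrastive terms — on the source domain and,
as an identity term, on the target domain — with `λ_X = λ_Y = 1`.

Aggregation over locations and layers is by *mean*, not sum: the uniform
logit closed form then reduces to `log(S)` per location regardless of `S`,
which is the anchor the unit tests pin.

Training follows the standard full-scale protocol for this model class — Adam
(`β₁ = 0.5, β₂ = 0.999`), learning rate `2·10⁻⁴`, batch size one,
200 epochs with the rate constant for 50 epochs and then linearly decayed
to zero — and the defaults of `train_config()` encode exactly that. The
generator trains on the standard non-saturating surrogate
(`−log D(G(x))`); the logged `L_GAN` column reports the literal value
function `E[log D(y)] + E[log(1 − D(G(x)))]`.

### Design choices that differ from the classic recipe, and why

* **Global residual output.** By default (`generator_spec(residual_output
  = TRUE)`) the network predicts a *correction* added to its input instead
  of synthesizing the output directly. At desk scale (tens of slices,
  hundreds of optimizer steps, one CPU) a direct-synthesis generator
  starting from random weights cannot reach identity-quality output, and
  every downstream property would silently measure initialization noise.
  The residual form makes the untrained model the identity map, aligns
  with the anatomical-consistency motivation, and leaves the classic head
  available behind the flag.
* **He initialization, no normalization in the discriminator.** With the
  small channel counts used here, a fixed small init SD shrinks
  activations several-fold per layer and the adversarial game never gets
  traction; He scaling keeps activations O(1). The patch discriminator
  carries no instance norm: per-image patch statistics (mean shifts from
  shading, variance shrink from contrast compression) are precisely the
  real-vs-fake cues at this scale, and instance norm would cancel them.
* **Windowed output.** Following the normalize → network → inverse-map
  design, the sCT lives inside the HU window. Out-of-window artifact
  excursions in the CBCT (noise and streak tails beyond the window edges)
  are therefore clipped even before the learned correction acts. In the
  desk-scale fidelity experiments this clipping contributes part of the
  measured MAE improvement; the learned correction contributes the rest
  (the test suite's trained model clearly beats both the raw CBCT and the
  untrained — identity-plus-initialization-noise — model).
* **Scaled-down schedules.** Micro-runs (4–24 epochs) hold the learning
  rate constant: compressing a 200-epoch schedule into a few hundred steps
  leaves no room for a decay tail. The schedule asserted by the acceptance
  tests is the full-scale default, which is untouched.

## Registration model

Registration is log-domain diffeomorphic demons. The energy is
`E(φ) = ‖I_m∘φ − I_f‖² + λ‖∇u‖²` with the smoothness penalty taken on the
*displacement* `u = φ − Id`, so the identity transform scores zero; the
literal gradient of φ would penalize the identity, which cannot be the
intent of a registration energy. `λ` (default 1) is diagnostic: as is
standard for demons, regularization is performed by Gaussian smoothing,
not by an explicit gradient of the penalty.

Each iteration computes the classic normalized demons force
`diff · ∇w / (|∇w|² + diff²/ξ²)` (with `ξ` the mean voxel size), caps its
magnitude at `step_bound_mm` (2 mm), smooths it with the fluid kernel
(`σ_fluid = 2` mm), accumulates it into a stationary velocity field `V`
(first-order log-domain composition `V ← V + v`, a
Baker–Campbell–Hausdorff truncation valid for small steps), smooths `V`
with the diffusion kernel (`σ_diffusion = 1` mm), zeroes the boundary
ring, and exponentiates by scaling-and-squaring (6 squarings). An update
that would raise the energy is rejected and retried at half step scale
(three strikes ends the level), so the accepted-energy trace is
non-increasing. Multi-resolution proceeds coarse-to-fine over 3 levels of
2× block-mean downsampling.

The exponential parameterization is what keeps `Id + u` diffeomorphic; the
test suite verifies positive Jacobian determinants by finite differences
and checks `exp` against a dense Euler integration of the flow ODE on
linear velocity fields (interior error ≤ 0.05 voxel at 8 squarings).

## Metrics

DSC is `2|A∩B|/(|A|+|B|)`; two empty masks score 1 with a warning, one
empty mask scores 0. Surface distances use face-connectivity borders (a
mask voxel with any face neighbour outside the mask; the array edge counts
as outside), physical-mm distances from the grid spacing, and *pooled
symmetric* multisets; HD95 is the 95th percentile by linear interpolation
(quantile type 7) and ASD the mean of the pooled multiset. These
conventions vary across the literature and silently change reported
values, so each is locked by an exhaustive brute-force oracle test on
masks up to 24³, including anisotropic (0.977, 0.977, 5) mm spacing.
Cohort aggregates are computed over per-case values, never voxels, with
the `Average` row aggregating per-case across-structure means.

## The phantom world

A phantom slice is an ellipse of soft tissue (≈30 HU) with a subcutaneous
fat rim (−90 HU), a heart-like disk (45 HU), and nested targets: CTV2
(40 HU) containing the small tumour-bed CTV1 (55 HU) — deliberately
low-contrast, as the clinical soft-tissue target is. Air is −1000 HU, and
a smooth within-tissue texture (12 HU amplitude, 8 mm correlation length)
gives registration something to grip. Inter-fraction change is a smooth
random displacement (Gaussian-filtered white noise, 20 mm correlation,
3 mm maximum amplitude, boundary-tapered to zero, verified
positive-Jacobian). The CBCT degradation applies contrast compression
(factor 0.65 about the in-body mean), an additive low-frequency bias field
(60 HU peak, 40 mm correlation), 8 oriented streaks (up to 40 HU), and
Gaussian noise (SD 25 HU). These amplitudes were fixed once as plausible
for clinical CBCT; they are a stand-in, not a claim about any scanner.

What a green test does establish: the analytics of the losses, the
numerics of the exponential map and the metrics, recovery of known smooth
deformations from clean images, and the *direction* of the two-arm
comparison under the stated degradations. What it does not establish:
clinical image quality, absolute clinical-cohort DSC/HD95/ASD, behaviour
under real scatter physics, 3D training, or anatomical variability beyond
the phantom's geometry.

## The two-arm experiment

`run_cohort()` generates `n` cases (planning image + contours, ground-truth
deformation, degraded CBCT, reference contours obtained by carrying the
planning contours through the ground-truth deformation — standing in for
physician delineation), trains or accepts a translator, and runs both arms
with byte-identical demons settings (asserted by config hash): arm A fixes
on the CBCT, arm B on `translate(CBCT)`. At the desk-scale defaults
(64² slices at 2 mm, 40 training slices, 24 constant-rate epochs) the
sCT-assisted arm matches or exceeds the direct arm on the low-contrast
CTV1 analogue — the clinical claim of the workflow, reproduced as a
directional property. The margin is small: the residual-mode translator
clips out-of-window artifact tails and learns low-frequency corrections,
but a few hundred CPU steps of adversarial training cannot restore deep
soft-tissue contrast, which is the regime where the full-scale method
earns its largest gains. Expect the gap to grow with training budget, not
with tuning.

## Numerical and interface choices

* Voxel indices are 0-based with `physical = origin + index · spacing`;
  displacement fields are stored in mm on physical axes, so metric
  distances are exact under anisotropic spacing.
* Interpolation clamps to the edge during warping/composition;
  out-of-domain resampling takes a fill value (default: minimum intensity,
  the CT air convention). Label maps always use nearest-neighbour and stay
  binary.
* NIfTI-1 I/O is a minimal built-in implementation (no NIfTI package
  exists in the target R stack): little-endian single-file `.nii`/
  `.nii.gz`, float64 on write (lossless round trips), sform geometry,
  vector-intent fields for DVFs.
* Configs serialize as JSON (`save_config`/`load_config`); the schema is
  flat and class-tagged. YAML was the original interface intent but no R
  YAML parser is available in the target environment.
* Rigid pre-alignment optimizes mean squared difference with a
  multi-start translation grid plus Nelder–Mead refinement; it recovers
  synthetic motions within 0.5 voxel / 1° on phantoms, which is all the
  pipeline requires of it.

## Known limitations

Training is 2D slice-wise (3D volumes translate per slice); the demons
engine supports 2D and 3D but all shipped experiments are 2D. The
adversarial translator at desk scale corrects low-frequency artifacts and
clips out-of-range excursions but does not meaningfully denoise or restore
compressed contrast; consequently the two-arm margin on phantoms is small
and seed-sensitive, whereas full-scale clinical applications of this
workflow report consistent gains. The demons implementation is intensity(SSD)-driven by design —
that fragility on artifact-laden CBCT is not a bug but the phenomenon
under study.
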