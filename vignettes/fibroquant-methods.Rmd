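---
title: "Quantifying lung inflammation and fibrosis with dual-echo UTE MRI and collagen PET: methods and design"
author: "fibroquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fibroquant methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroquant)
```

## The measurement problem

Intratracheal bleomycin in the rat produces an acute inflammatory lung
injury (peaking around one week) that evolves into patchy fibrosis over
three to four weeks. Two non-invasive readouts can track this course:

* **Dual-echo UTE MRI.** Ultra-short-echo-time sequences sample the signal
  fractions of a millisecond after excitation. At a short echo time
  (TE 0.324 ms) essentially all tissue — fluid, soft tissue, and
  short-T2\* fibrotic tissue — is visible; at a longer echo (TE 1 ms) only
  long-T2\* fluid (blood, inflammatory edema) retains signal, because
  signal decays as $\exp(-\mathrm{TE}/T_2^*)$. Lesions bright at *both*
  echoes are fluid-dominated ("edema"); lesion voxels bright *only* at the
  short echo indicate the fibrosis-associated "tissue" compartment.
* **Collagen-binding PET.** A Cu-64-labelled collagen-binding peptide
  recognises non-cross-linked collagen-I, i.e. newly synthesised fibrils.
  Its uptake concentrates not inside established lesions but at their
  rim, where active fibrogenesis happens. Uptake is reported as percent
  of the injected dose (%ID) per region.

The package implements the complete analysis — lesion extraction,
compartment decomposition, ROI transfer to the PET frame, %ID and
border-ring quantification, ΔΔCt gene expression, and significance-symbol
reporting — and validates it end to end on digital rat-thorax phantoms
with known ground truth, since no deposited imaging data exist for this
model.

## The phantom

`make_label_map()` builds a voxelised thorax: an ellipsoidal body of
muscle/organ tissue, two ellipsoidal lung fields, one to three finite
cylindrical vessels per lung, and patchy lesions grown from randomly
seeded blob centres inside the lung. Each voxel carries one of seven
classes (`tissue_labels()`): background, muscle/organ, lung parenchyma,
vessel, edema, fibrotic tissue, and *active border* — the one-voxel
(6-connectivity) shell of parenchyma adjacent to any lesion voxel, which
is invisible on MRI but carries the highest PET tracer density, emulating
collagen synthesis at the lesion rim.

The longitudinal disease course is a `trajectory_spec()`: target edema
and tissue volumes per imaging day (0, 7, 14, 21, 28), shaped as gamma
curves $A\,(t/m)^k e^{k(1-t/m)}$ with the edema mode pinned at day 7
(default peak 800 mm³, $k=2$) and the tissue mode at day 28 (default peak
500 mm³, $k=3$). Day-0 volumes are zero. Defaults were chosen once as a
realistic bleomycin course — lesion burden in the 5–10 % range of a
roughly 12 mL two-lung volume — and are configurable. Lesion voxel counts
match the targets to within half a voxel; blob geometry derives from the
trajectory seed alone, so lesions of one series grow and shrink in place
across days. Edema occupies blob cores and fibrotic tissue the rim,
so the fibrotic fraction grows as inflammation resolves.

### Signal models

* **MRI**: noise-free signal is mono-exponential,
  $S = \rho \exp(-\mathrm{TE}/T_2^*)$ per class, with default proton
  densities (a.u.) lung 15, muscle 80, vessel 100, edema 95, fibrotic 70
  and $T_2^*$ (ms) 0.5, 8, 20, 15, 0.7. Fluid classes therefore lose
  under 7 % of signal between echoes while fibrotic tissue drops to 38 %,
  which is the contrast the decomposition exploits. Noise is Rician —
  the magnitude of complex-Gaussian data,
  $\sqrt{(S+\sigma N_1)^2+(\sigma N_2)^2}$. SNR is quoted against the
  brightest class (proton density 100), so SNR 20 means $\sigma = 5$.
* **PET**: each class has a relative tracer density (active border
  highest among lung classes, default 8 vs. 2 for fibrotic tissue, scaled
  further by the trajectory's per-day border-uptake factor). Densities
  are converted to MBq/mL by a *healthy-lung calibration*: the scale is
  chosen so that a lesion-free lung of the same geometry would contain
  `lung_dose_fraction` (default 1 %) of the injected dose (drawn from
  35 ± 5 MBq per series). Lesions and border then add uptake on top, so
  diseased lungs hold a larger dose fraction than controls — the group
  difference the tracer is designed to show, while the lesion-free
  conservation oracle stays exact. The concentration map is resampled to
  the 0.4 mm PET grid by exact box-overlap averaging, blurred with a
  1 mm FWHM Gaussian point-spread function, and Poisson-perturbed at a
  configurable counts-per-MBq scale (`1e7` by default, i.e. tens of
  counts per lung voxel).

Scanner physics deliberately *not* modelled: radial k-space sampling and
reconstruction, attenuation, scatter, randoms, respiratory motion (the
acquisitions this emulates were non-gated). The phantoms exercise the
*analysis* — thresholding, mask algebra, resampling, %ID bookkeeping —
on reconstructed-volume inputs; passing tests demonstrate correctness of
that analysis under the stated noise models, not robustness to
acquisition artefacts, partial-volume effects at real parenchymal
texture, or segmentation ambiguity in real anatomy.

The default working grid is 96³ voxels at 0.6 mm (57.6 mm field of view);
`full_mri_grid()` provides the acquisition-matched 192 × 192 in-plane
geometry. All problem sizes in the tests use the 96³ grid.

## Lesion extraction and decomposition

Within a lung ROI (supplied, as in semi-manual practice, or segmented
automatically from the short echo by Otsu body extraction, two largest
dark components, hole filling), lesions are the "high-signal area"
defined by within-lung histogram analysis (`lesion_mask()`):

* `mode_mad`: median of within-lung intensities + $k\cdot$MAD
  ($k = 4$). The aerated parenchyma dominates the ROI, so this tracks the
  dark mode and cuts just above its noise tail.
* `otsu`: Otsu's between-class-variance threshold, with the cut placed at
  the upper edge of the maximising bin (values strictly above the
  threshold are lesion).

The defaults differ per echo, by the physics of what "high signal" means
on each: on the short echo (total signal) every non-aerated voxel is
lesion candidate, so `mode_mad` is used; on the long echo (fluid signal)
the lesion ROI is the bright *fluid mode* of a bimodal histogram, so
`otsu` is used. A single rule on both echoes fails in a characteristic
way: `mode_mad` on the long echo puts the threshold within one noise SD
of the fibrotic class (which at $T_2^*=0.7$ ms retains ~24 % of its
signal at TE 1 ms) and misclassifies clustered fibrotic voxels as edema,
while `otsu` on the short echo can cut *above* the fibrotic cluster when
the fibrotic burden is small. Both single-rule variants remain available
(`threshold_rule = "mode_mad"` or `"otsu"`).

Connected components under 5 voxels are removed from lesion masks (noise
suppression; set `min_size = 0` to disable — with it disabled, noise-free
recovery is voxel-exact). Thresholds use strict `>` comparison, so a
degenerate zero-MAD histogram still excludes the majority value; a
constant within-lung histogram raises an error.

Compartments follow from ROI set algebra, after subtracting the vessel
mask from both per-echo lesion ROIs:

$$\mathrm{edema} = L_{\mathrm{long}} \setminus V, \qquad
  \mathrm{tissue} = (L_{\mathrm{short}} \setminus V) \setminus
  L_{\mathrm{long}}.$$

The two are disjoint by construction. The package implements the
compartments as ROI differences (not voxelwise signal differences); the
vessel mask is an explicit input (phantom truth or user-drawn) — no
tubularity heuristic is invented. Each echo is thresholded against its
own histogram.

## PET quantification

* **Mask transfer** (`transfer_mask()`): fractional-occupancy resampling;
  a target voxel is set when ≥ 0.5 of its volume is mask-covered
  (exact box overlap for axis-aligned grids, 3³ supersampling under a
  user-supplied rigid transform; exact half-coverage counts as occupied,
  with a 1e−9 tolerance). Default transform is the identity, matching
  co-simulated/co-registered frames; no automatic registration is
  attempted.
* **%ID** (`percent_id()`):
  $100 \sum_v c_v \cdot V_{\mathrm{vox}} / D$ with $c$ in MBq/mL and $D$
  the injected dose in MBq. Additive over disjoint masks by construction.
* **Decay correction** (`decay_correct()`): activity scaled by
  $2^{\Delta t / T_{1/2}}$, $T_{1/2} = 12.7$ h (Cu-64), referred to
  injection time by default. Whether %ID should be decay-corrected is
  left open by common practice, so `compartment_uptake()` emits both raw
  and corrected columns (at a 60 min delay the factor is
  $2^{1/12.7} \approx 1.056$).
* **Ring profile** (`ring_profile()`): lung voxels binned by signed
  Euclidean distance (exact anisotropic transform) to the lesion
  boundary. Ring 0 is the boundary shell itself — voxels within half a
  ring width (default width 0.8 mm = two PET voxels) of the surface on
  either side; positive rings step outward, negative inward. The
  straddling definition is deliberate: after 1 mm PSF blur the uptake of
  a 0.6 mm border shell peaks *on* the boundary, and an outside-only
  ring 0 would make the argmax an arbitrary coin flip between −1 and 0.
* **"Surrounding"**: the whole remaining lung,
  $\mathrm{lung}\setminus(L_{\mathrm{short}}\cup L_{\mathrm{long}})$, is
  reported as a compartment; note that over so large a region mean
  concentration dilutes away, so border localisation should be read from
  the ring profile, which *is* the margin-resolved version of
  "surrounding".

## ΔΔCt quantification

`delta_ct()` references each target gene to the arithmetic mean of the
two reference-gene CTs (B2M, RLP13a) — equivalent to the geometric mean
of reference expression on the $2^{-CT}$ scale. `relative_expression()`
then normalises to the control group at the same time point. The
calibrator is applied on the linear expression scale,
$\mathrm{rel}_i = 2^{-\Delta CT_i} / \overline{2^{-\Delta CT}}_{\mathrm{ctrl}}$,
so the control-group arithmetic mean is exactly 1 per (gene, day); the
classical log-scale calibrator ($\Delta\Delta CT$ against the mean
control $\Delta CT$, whose control *geometric* mean is 1) is emitted
alongside, and the two coincide for a single control sample.
Amplification efficiency is fixed at 2 (no standard-curve correction).
SEM is reported on the fold-change scale, with the log2-scale SEM as an
additional column, since which scale a given figure uses is often
unstated.

## Statistics and symbols

`compare_groups()` delegates to standard routines — one-way ANOVA with
Bonferroni-adjusted pooled-SD pairwise t tests, or pairwise Mann–Whitney
(Wilcoxon rank-sum) — and only orchestrates comparisons and applies the
symbol policy. Both methods are first-class because longitudinal
preclinical reports commonly mix them without per-figure attribution;
the choice is a recorded config flag. Symbols
(`assign_symbol()`): one glyph per tier, p < 0.05/0.01/0.001/0.0001,
with `*` for bleomycin-vs-control at the same day, `#` for between-day
comparisons within the bleomycin group, and `§` for vs-baseline within a
group.

## Numerical choices and degenerate inputs

* Box-overlap resampling conserves the activity integral exactly over a
  covering destination grid; `simulate_pet()` refuses a PET grid that
  does not cover the phantom.
* Distance transforms are exact (Felzenszwalb–Huttenlocher, anisotropic
  spacing), computed in C++; connected components are 6-connectivity.
* Gaussian blur uses a normalised truncated (±3σ) separable kernel with
  zero padding; mass is conserved in the interior, not at volume edges.
* Empty lung masks, empty lesion masks (ring profile), constant
  histograms, non-invertible transforms, unknown class ids, day values
  outside the trajectory, and lesion targets exceeding the lung volume
  all raise immediate errors.
* One global seed fans out to per-stage seeds through a stable string
  hash (`derive_seed()`), keeping every stage individually reproducible
  and all derived seeds below $2^{31}$.

## Worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(seed = 1)
res <- run_pipeline(cfg, "run1")

# estimated compartment volumes per day
subset(res$summary, compartment %in% c("edema", "tissue"),
       select = c(day, compartment, volume_mm3))

# recovery against phantom ground truth
res$recovery

# uptake per compartment, day 28
subset(res$uptake, day == 28)
```

## Known limitations

* The phantom's parenchyma is homogeneous; real aerated lung has texture
  that would widen the within-lung histogram and make the 4-MAD rule less
  clean. Real vessel trees are not tubular cylinders.
* No partial-volume correction is applied to PET compartments; small
  compartments inherit the usual spill-in/spill-out bias, visible in the
  phantom as %ID differences between the label-grid and PET-grid
  estimates.
* No inter-timepoint registration: series are assumed co-registered, as
  co-simulated phantoms are.
* The automatic lung segmentation is a surrogate for semi-manual ROI
  drawing and is validated only against the phantom geometry
  (Dice ≥ 0.9); it is not a general rodent lung segmenter.
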