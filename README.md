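# fibroquant

Quantitative imaging analysis for the rat bleomycin model of lung
injury: decomposes lung lesions seen on dual-echo ultra-short-echo-time
(UTE) MRI into an inflammatory fluid ("edema") compartment and a
fibrosis-associated ("tissue") compartment, and quantifies the uptake of
a collagen-binding Cu-64 PET tracer per compartment as percent injected
dose (%ID), including distance-ring profiles that resolve the tracer's
accumulation at the border between lesions and healthy lung. It is aimed
at preclinical imaging scientists who need a reproducible, testable
version of this analysis, validated end to end on digital phantoms with
known ground truth.

## The analysis in brief

MRI signal decays as *S* = ρ·exp(−TE/T2\*). At a short echo time
(TE 0.324 ms) all tissue is visible; at TE 1 ms only long-T2\* fluid
remains. Within a lung ROI, per-echo lesion masks are extracted by
within-lung histogram thresholding (median + 4·MAD above the
aerated-parenchyma mode on the short echo; Otsu's bimodal split on the
long echo), the vessel mask *V* is subtracted, and the compartments are
ROI differences:

    edema  = L_long \ V
    tissue = (L_short \ V) \ L_long

The MRI ROIs are transferred to the 0.4 mm PET grid by
fractional-occupancy resampling (a voxel is set at ≥ 0.5 coverage), and
uptake is quantified as

    %ID = 100 · Σ (activity · voxel volume) / injected dose

with Cu-64 decay correction 2^(Δt / 12.7 h), plus mean uptake binned by
signed Euclidean distance to the lesion boundary (ring 0 = the boundary
shell). A seeded phantom generator reproduces the model's course — edema
volume peaking at day 7, fibrotic tissue at day 28, tracer concentrated
at the active lesion border — so every estimator can be checked against
ground truth. A ΔΔCt module (dual reference genes B2M/RLP13a, per-day
control normalisation) and tiered significance symbols (\*/#/§ per
comparison family) cover the downstream reporting.

## Worked example

```r
library(fibroquant)
cfg <- pipeline_config(seed = 1)          # 96^3 phantom, SNR 20
res <- run_pipeline(cfg, "run1")
subset(res$summary, compartment %in% c("edema", "tissue"),
       select = c(day, compartment, volume_mm3))
```

```
 day compartment volume_mm3
   0       edema       0.00
   0      tissue       0.00
   7       edema     800.06
   7      tissue      73.44
  14       edema     433.08
  14      tissue     279.50
  21       edema     131.98
  21      tissue     446.26
  28       edema      31.54
  28      tissue     499.61
```

The measured edema volume peaks at day 7 and the tissue volume at day
28, tracking the simulated disease course (this run's ground-truth
targets were 800.1/74.1 mm³ at day 7 and 31.8/500.0 mm³ at day 28 —
recovery errors under 1 %). PET uptake for the same run at day 28:

```r
subset(res$uptake, day == 28, select = c(compartment, volume_mm3, percent_id))
```

```
  compartment volume_mm3 percent_id
   total_lung   15887.62    2.51427
 lesion_short     585.73    0.63216
  lesion_long      38.34    0.01931
        edema      38.34    0.01931
       tissue     561.22    0.62041
  surrounding   15301.89    1.88211
```

The diseased lung holds 2.51 %ID against ~1.1 %ID for a lesion-free
control at the same dose, and most of the uptake sits *outside* the
MRI-defined lesions (`surrounding`), because the phantom — like the
biology it emulates — concentrates the collagen tracer at the lesion
border; `ring_profile()` shows the peak in the boundary ring. The
`res$recovery` table compares every estimate with the phantom ground
truth per day.

For the ΔΔCt module:

```r
ct <- read_ct_table(system.file("extdata", "synthetic_ct_table.csv",
                                package = "fibroquant"))
res <- relative_expression(ct)             # control means are exactly 1
```

See `vignette("fibroquant-methods")` for the models, parameter defaults,
and design decisions.

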