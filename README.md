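# tmsmap

Regression-based TMS motor cortex mapping with three neuronal response
models.

## What it does and for whom

Single-pulse TMS over the motor cortex evokes MEPs, but the induced
electric field covers far more cortex than the neurons that actually
produce the response. `tmsmap` is for researchers who localize cortical
muscle representations the regression way: deliver hundreds of pulses
from randomized coil placements, compute the per-pulse E-field on a
cortical ROI, and at every surface element fit the sigmoidal
input–output curve

    ŷ = y0 + (a − y0) / (1 + exp(−r (x − x0)))

of MEP amplitude `y` against a field quantity `x`, scoring each element
by

    R² = 1 − VAR(y − ŷ) / VAR(y).

The masked R² peak — restricted to precentral elements where at least
25% of pulses delivered |E| > 40 V/m — is the estimated cortical origin
(hotspot). Three choices of `x` define the *neuronal response models*:

| model | quantity | layer |
|---|---|---|
| magnitude | `\|E\|` | midlayer (depth 0.5) |
| cosine | `\|E⊥\| = \|E\|·\|cos θ\|` | midlayer |
| neuron | `E_eff = \|E\| / S(θ, Δ\|Ẽ\|)` | L5 (depth 0.65) |

where θ is the polar angle between the field and the somato-dendritic
axis, Δ|Ẽ| the relative depth gradient of |E| (%/mm), and S a
normalized firing-threshold look-up table with S(0,0) = 1.

The package covers the full study workflow: layered surface geometry
with geodesic distances, per-element sigmoid regression (multi-start
bounded Levenberg–Marquardt in C++), pulse-subsampling convergence
analysis (NRMSD and hotspot-distance metrics, 5% / 1 mm thresholds),
exhaustive coil-placement optimization (20 mm / 2 mm / 360° / 4° grid =
27450 configurations), 10 mm shifted control placements, and the
validation statistics `log(MEP) ~ placement + (1|subject)` with
Holm-corrected post-hoc contrasts. A synthetic gyral phantom with an
analytic figure-of-eight primary field and a hidden ground-truth
element makes everything runnable and testable without MRI, FEM or
hardware; see the methods vignette
(`vignettes/tms-mapping-methods.Rmd`) for the model assumptions and
numerical choices.

## Worked example

```r
library(tmsmap)

# build the synthetic gyral phantom and its midlayer geometry
phantom <- gyral_phantom()
phantom
#> gyral_phantom: 1568 elements, 392 in the precentral band
true_elem <- phantom_true_element(phantom)
mid <- layer_inputs(phantom, depth = 0.5)

# 500 random coil placements within 30 mm / ±60° of the reference
ref <- reference_placement(phantom)
scale <- calibrate_primary_scale(ref, mid$frames$centroid[true_elem, ])
pulses <- sample_coil_placements(ref, 500, seed = 7, scalp = phantom$scalp)

# |E| per pulse and element, and MEPs from the hidden ground truth
x <- model_quantity("magnitude", pulses, mid, scale = scale)
truth <- ground_truth(true_elem, y0 = 0.02, a = 2, r = 0.1, x0 = 60,
                      noise_sd_log = 0.3)
meps <- generate_meps(truth, x[, true_elem], seed = 8)

# per-element sigmoidal regression and hotspot extraction
map <- localize(x, meps, attr(x, "emag"), phantom$stack$gm$labels)
map
#> r2_map (magnitude model): 392/1568 elements masked in,
#>   hotspot element 405 (R2 = 0.808), n = 500 pulses
geodesic_distance(mid$mesh, map$hotspot, true_elem)
#> [1] 0
fit_sigmoid(x[, map$hotspot], meps)
#> sigmoid_fit: y0=0 a=2.139 r=0.08459 x0=61.14  R2=0.8084 (n=500)
```

The regression finds the planted origin exactly (geodesic error 0 mm)
and recovers the IO curve: saturation 2.14 mV vs the true 2 mV, turning
point 61.1 V/m vs the true 60 V/m, with R² = 0.81 under 30% log-normal
MEP noise. From a map, `sequential_maps()` quantifies how many pulses
the localization needs to stabilize, `make_search_grid()` +
`optimize_placement()` find the coil placement maximizing the model's
quantity at the hotspot, and `simulate_validation()` +
`fit_placement_lmm()` compare it against the shifted controls.
`run_study()` chains all stages from a single seeded `study_config()`
and writes self-describing artifacts; a command-line wrapper is in
`inst/cli/tmsmap.R`.

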