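---
title: "Regression-based TMS motor mapping: models, assumptions and numerical choices"
author: "tmsmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regression-based TMS motor mapping: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmsmap)
```

## The problem

Transcranial magnetic stimulation (TMS) over the primary motor cortex
elicits motor-evoked potentials (MEPs) in hand muscles, but the induced
electric field (E-field) spreads over several square centimeters of
cortex, so the scalp position of the coil says little about *which*
cortical elements actually generated the response. Regression-based
mapping turns this around: many single pulses are delivered from
randomized coil positions and orientations (within about 3 cm and
±60° of a reference placement), the E-field of every pulse is
computed on a cortical region of interest, and at every surface element
the per-pulse field quantity is regressed against the measured MEP
amplitude with a sigmoidal input–output (IO) curve,

$$\hat y_{i,j} = y_0 + \frac{a_j - y_0}{1 + e^{-r_j (x_{i,j} - x_{0,j})}},$$

where $x_{i,j}$ is the field quantity of pulse $i$ at element $j$,
$y_0$ is the noise floor (mV), $a$ the saturation amplitude (mV), $r$
the slope (per V/m), and $x_0$ the turning point (V/m). The goodness of
fit per element,

$$R^2_j = 1 - \frac{\mathrm{VAR}(y - \hat y_j)}{\mathrm{VAR}(y)},$$

peaks at the cortical origin of the MEPs: only there does the local
field consistently explain the response. The masked $R^2$ maximum is
the *hotspot*.

`tmsmap` implements this pipeline for three *neuronal response models*,
i.e. three choices of the regressor $x$:

* **magnitude model** — $|E|$ on the midlayer surface (halfway between
  the gray-matter and white-matter surfaces);
* **cosine model** — $|E_\perp| = |E||\cos\theta|$, the absolute field
  component along the somato-dendritic axis (the classical cortical
  column cosine assumption), also on the midlayer;
* **neuron model** — the effective field
  $E_{\mathrm{eff}} = |E| / S(\theta, \Delta|\tilde E|)$ on layer 5,
  where $S$ is a normalized firing threshold looked up as a function of
  the polar angle $\theta$ between field and axis and of the relative
  depth gradient of the field magnitude $\Delta|\tilde E|$ (%/mm), with
  $S(0, 0) = 1$. $S > 1$ marks orientations that need a stronger field
  to fire.

The package also implements the downstream study stages: convergence
analysis over randomized pulse subsamples, exhaustive coil-placement
optimization at the hotspot, shifted control placements, and the
mixed-model statistics of a validation experiment.

## Geometry

Cortical layers are represented as a `layer_stack`: vertex-corresponding
GM and WM triangulations with layer surfaces linearly interpolated at
normalized depths (0 = GM, 1 = WM). The canonical depths are L1 0.06,
L2/3 0.4, L4 0.55, L5 0.65, L6 0.85; the midlayer sits at 0.5, the only
sensible reading of "halfway between the surfaces". Per element, the
somato-dendritic axis is the unit vector from the WM to the GM element
centroid — robust on coarse meshes and exactly consistent with the
layer construction; averaged vertex normals would differ only at sharp
folds. All quantities are evaluated element-wise (at triangle
centroids), not vertex-wise.

Geodesic hotspot distances use Dijkstra shortest paths on the mesh edge
graph augmented with element-centroid nodes (each centroid connected to
its triangle's vertices). This overestimates true polyhedral geodesics
by at most roughly one edge length, well below the 1 mm convergence
threshold at the mesh resolutions used; exact polyhedral geodesics were
deemed unnecessary. The triangle inequality and a brute-force
Floyd–Warshall oracle are asserted in the tests.

## The synthetic phantom

Real data for this pipeline require MRI-based head models and FEM field
solutions. To make every stage testable, `gyral_phantom()` builds a
sinusoidal gyral ribbon: GM surface $z = A\cos(2\pi x/\lambda)$
(defaults: amplitude 4 mm, wavelength 20 mm, 60 × 40 mm sheet,
29 × 29 vertices → 1568 elements), WM offset 2.5 mm inward along the
local normal (a typical cortical thickness), a central band of elements
labeled `"precentral"`, and a planar scalp 15 mm above the crowns. A
0.15 mm seeded in-plane vertex jitter breaks the lattice symmetry so
ties are measure-zero.

The primary E-field of a placement is the superposition of two opposed
magnetic dipoles offset ±20 mm along the coil x axis with moments
along the coil normal — a smooth figure-of-eight-like field that decays
with distance, rotates rigidly with the coil, and runs along the
current direction beneath the coil center. It is a *geometric* test
field: it reproduces the placement-dependence and crown/wall contrast
the analysis relies on, but it is not a physics substitute for a FEM
solution (no charge accumulation, no conductivity boundaries). The
field scale is calibrated so that the reference placement delivers
100 V/m at the true element at mapping intensity, putting the sigmoid
turning point (60 V/m) in the realistic mid-range of the sampled
fields.

MEPs are drawn as $\mathrm{sigmoid}(x)\cdot e^{\varepsilon}$ with
$\varepsilon \sim N(0, \sigma^2)$, $\sigma = 0.3$ by default, floored
by an independent draw around the noise floor $y_0$ — multiplicative
log-normal noise matches the strong right skew of measured MEPs and the
log transform used in the validation statistics. Default IO parameters
($y_0 = 0.02$ mV, $a = 2$ mV, $r = 0.1$ per V/m, $x_0 = 60$ V/m) give
FDI-like 0–4 mV responses.

**Ground-truth element.** The simulated MEP origin defaults to a
*crown-rim* element (|x| near λ/8, the shoulder of the central gyrus)
rather than the crown center. This is deliberate: hand-muscle
representations sit on the crown and rim of the precentral gyrus, and
identifiability requires it — at the exact crown center the
somato-dendritic axis is vertical while the induced field stays nearly
tangential, so $\theta \approx 90°$ for every placement, the threshold
$S$ barely varies, and $E_{\mathrm{eff}}$ collapses onto a rescaled
$|E|$ (their per-pulse correlation exceeds 0.998 there). At the rim the
axis is tilted ~40°, $\theta$ varies with coil position and rotation,
and the three models make distinguishable predictions.
`phantom_true_element(location = "crown")` restores the degenerate
variant.

**Surrogate threshold table.** The published average-threshold tables
are not reproduced here; `surrogate_lut()` provides the qualitative
shape instead: $S = (1 + \kappa(1 - |\cos\theta|))(1 + s\,\Delta)$,
normalized to $S(0,0) = 1$, symmetric about $\theta = 90°$, with
moderate angular tuning $\kappa = 0.3$ (at 90° the effective field is
$|E|/1.3$ — between the cosine model's 0 and the magnitude model's
$|E|$) and a weak gradient slope $s = 0.005$ per %/mm. With
$\kappa = s = 0$ it is the identity table and the neuron model reduces
exactly to the magnitude model (asserted in the tests). Any externally
supplied table in the same long CSV format is accepted by `read_lut()`.

## Field quantities

The depth gradient is sampled at 10% of the distance from the layer
toward the GM surface (shallow) and toward the WM surface (deep):

```{r}
gradient_sample_depths(0.65) # layer 5
```

and computed as
$100\,(|E|_{\mathrm{deep}} - |E|_{\mathrm{shallow}})/(|E|_{\mathrm{layer}}\cdot d)$
in %/mm, where $d$ is the geometric distance between the two sampling
points. The sign convention — positive when the field grows toward the
WM — is a package choice (only the magnitude of change is prescribed by
the units); a two-sided difference is used because a one-sided reading
of "toward the GM or WM surface" is ambiguous. On an exponential
depth-decay field this two-point estimate matches the analytic
log-derivative within 1%. Look-ups outside the table's gradient range
clamp to the boundary (precomputed tables have finite support) and the
clamped fraction is reported as an attribute. Elements with zero field
have undefined $\theta$ and are masked out of the regression.

## Fitting and masking

Each element is fitted independently by bounded Levenberg–Marquardt
least squares (implemented in C++ for the ~10^5 fits of a convergence
run) with analytic Jacobian and box constraints
$y_0 \in [0, \mathrm{med}(y)]$, $a \in [\mathrm{med}(y), 2\max(y)]$,
$r > 0$, $x_0 \in [\min(x), \max(x)]$. Five multi-starts are used: a
data-driven heuristic ($y_0 \leftarrow q_{05}(y)$,
$a \leftarrow q_{95}(y)$, $x_0 \leftarrow \mathrm{med}(x)$,
$r \leftarrow 4/\mathrm{IQR}(x)$) plus four log-normally jittered
variants drawn under a configurable seed, so fits are bit-reproducible.
The optimizer, initialization and bounds are package choices — the
study protocol does not prescribe them — and the suite cross-checks the
fits against an independent Levenberg–Marquardt implementation
(`minpack.lm`). All four parameters are fitted per element; a shared
floor is a config option. Fits are done on the raw mV scale, matching
the variance-based $R^2$; negative $R^2$ values are kept (a map is
normalized only for display). Degenerate inputs (constant $x$) are
flagged, score $R^2 = 0$, and never become hotspots; argmax ties break
to the lowest element id.

Hotspot masking follows the protocol: an element is eligible only if it
carries the ROI label (`"precentral"`) and at least 25% of pulses
delivered $|E| > 40$ V/m there — the exposure rule that suppresses
spurious deep correlations caused by the field's spatial smoothness.
The fraction test is inclusive (exactly 25% passes).

## Convergence analysis

For each of `n_rand` randomized pulse orderings, maps are recomputed on
the first $n$ pulses over a schedule and compared with the full-N
reference and with the previous schedule entry, using two metrics: the
NRMSD

$$\mathrm{NRMSD} = \frac{\sqrt{\tfrac1{N_\mathrm{elm}}\sum_i (R^2_{i,n} - R^2_{i,\mathrm{ref}})^2}}{\max(R^2_\mathrm{ref}) - \min(R^2_\mathrm{ref})}$$

and the geodesic distance between hotspots; thresholds 5% and 1 mm.
"Meeting" a criterion is read as a *sustained* crossing — the metric
stays under threshold for every larger scheduled $n$ — because a single
lucky dip should not count as convergence; first-crossing is available
as a mode. The minimum pulse counts are averaged across randomizations.
Three numerical choices keep desk-scale runtime without changing the
answer materially: the element mask is frozen from the full-N reference
(so maps are always compared over identical elements; per-n recomputing
is a config option), each $n$ warm-starts from the $n-1$ solution
(agreeing with cold starts to well under the 5% criterion, asserted in
the tests), and the schedule step is configurable (the full protocol is
step 1 from 10 to 800 with 100 randomizations — 79100 maps, which the
package enumerates exactly; tests and the acceptance script run step 10
with 10 randomizations). Cross-model comparisons use the Friedman test
with Conover–Iman post-hoc contrasts (Bonferroni-corrected by default);
the Conover statistic is implemented from the rank-sum formula and
verified against hand computation, since no packaged implementation is
available here.

## Coil optimization and validation

The search grid is a square lattice (2 mm spacing) in the scalp tangent
plane around the projected hotspot, keeping points strictly inside a
20 mm radius, re-projected to the scalp, crossed with 90 in-plane
orientations at 4° — 305 × 90 = 27450 configurations, matching the
protocol's printed count; the strict inequality is the convention that
reproduces it, and the count contract applies to planar or near-planar
scalps (on a curved head the re-projection makes it position
dependent). The objective is the model's quantity at the hotspot
element; the exhaustive argmax and the full table are returned. The
four controls shift the optimal placement ±10 mm along the scalp
anatomical axes (on the phantom: anterior = +x across the gyrus,
superior = +y along it), orientation unchanged.

The validation experiment delivers 50 pulses per placement at 120% rMT
— realized as intensity 0.8 relative to the 150% rMT mapping intensity
— across the seven placements in per-subject randomized order, with a
log-normal subject random intercept (s.d. 0.5, a typical between-subject
MEP spread). The analysis fits `log(MEP) ~ placement + (1 | subject)`
with `lme4` (ML), tests the placement factor by likelihood ratio, and
back-transforms marginal means. Post-hoc contrasts are Holm-corrected
paired t tests on subject-level mean log MEPs with paired Cohen's d
(difference mean over difference s.d.) — subject-level pairing is the
only convention consistent with t statistics having subjects-minus-one
degrees of freedom, and trial-level pooling is not reconstructible from
reported group summaries. Amplitudes below 0.005 mV (an order below the
0.05 mV threshold criterion) are floored before the log. A singular
subject variance falls back to a fixed-intercept model, flagged.

The resting motor threshold helper scans an ascending 2% intensity
ladder and returns the lowest level at which at least 5 of 10 simulated
pulses reach 0.05 mV; an ascending scan is the reproducible equivalent
of manual threshold hunting.

## Reproducibility

All randomness flows from explicit seeds; pipeline stages derive
sub-seeds by a stable hash of (master seed, stage name), so any stage
can be re-run in isolation. `run_study()` writes self-describing CSV
artifacts (each header carries model, layer, units and the config hash)
plus a JSON manifest, and is bit-reproducible for a fixed
configuration. Mesh I/O uses ASCII PLY/OFF with a CSV label sidecar;
tables, look-up tables and traces are CSV; configuration is YAML.

## What the phantom does and does not show

Passing the end-to-end suite shows that the estimator chain —
quantities, masking, fitting, hotspot extraction, convergence metrics,
optimization, validation statistics — is internally correct and
recovers planted ground truth under realistic noise: at default
conditions (1568 elements, 500 pulses, noise 0.3) the hotspot is
recovered within 5 mm and the generating model is discriminated at the
true element. It does *not* show that any model is superior on real
cortex: the phantom's fields are dipolar, not FEM solutions; its
threshold table is a surrogate shape, not the published neuron
simulations; its geometry is a single idealized gyrus; and the cosine
model's disadvantage on real data (sulcal mislocalization) is only
partially reproduced by a sinusoidal fold. Quantitative results from
the human datasets — group-mean peak $R^2$, pulse counts in the
hundreds, millivolt marginal means — are properties of those datasets
and are not reproduced at phantom scale.

## Problem sizes used by the shipped runs

The test suite and acceptance script run the generator at its default
conditions for localization (1568 elements, 500 pulses, 20 seeds) and
at reduced scale for sequential analyses: a 512-element phantom,
convergence schedules of step 10 up to n = 400 with 10 randomizations,
and 8 simulated validation subjects. These sizes are the package's
choices for a single-workstation reproduction; every driver accepts the
full protocol parameters.
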