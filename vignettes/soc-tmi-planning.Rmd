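---
title: "Methods: conformal total marrow irradiation planning for the mouse"
author: "soctmi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformal total marrow irradiation planning for the mouse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Total marrow irradiation (TMI) is conditioning radiotherapy for
hematopoietic cell transplantation that targets the skeleton (the marrow
compartment) and the spleen while sparing the other organs, in contrast to
uniform total body irradiation. Translating TMI to the mouse is hard
because the organs that matter most — lungs and kidneys — lie directly
against the spine, millimetres from the target, and because preclinical
irradiators use kilovoltage photons whose photoelectric interaction
deposits far more dose in bone than in soft tissue.

`soctmi` implements and compares two preclinical planning approaches on a
synthetic digital mouse:

* a **conformal plan** (`plan_soc_tmi()`): seven equally distributed
  coplanar fields whose fluence maps are optimized by accelerated proximal
  gradient descent (FISTA) and then decomposed into weighted rectangular
  apertures deliverable by a sparse orthogonal collimator — four tungsten
  leaf pairs forming rectangles;
* a **parallel-opposed baseline** (`compute_3d_plan()`): seven anatomic
  regions, each irradiated by an opposed pair of fixed square or circular
  collimators with matched field edges, each region normalized to the
  prescription at its normalization point.

Dose-volume histograms, median/integral dose percentages, cohort
mean ± SD summaries and paired plan comparisons (`dvh` and metric
functions) quantify the difference.

## The synthetic phantom

`generate_phantom()` renders a prone mouse from analytic primitives
(ellipsoids and capsules): a soft-tissue body about 80 mm long, a skull, a
cranio-caudal vertebral column near the dorsal surface, shoulder girdle,
pelvis, femurs and tibias (together the skeletal target), a spleen, and
the organs at risk (lungs, kidneys, liver, heart, bowel). Two properties
are deliberate and tested:

* **adjacency** — the lungs and kidneys are constructed to overlap the
  spine's envelope; the overlap is carved away by bone-first priority,
  leaving them flush against the skeleton (within one voxel). This is the
  geometric feature that makes the baseline plan expose them;
* **analytic volumes** — every organ is a union of primitives with known
  volume, so voxelization and dilation can be tested against closed forms.

Densities default to soft tissue 1.00, lung 0.26 and cortical bone
1.85 g/cm³, standard tissue values. The native grid spacing is 0.5 mm, a
desk-scale stand-in for a ~0.2 mm cone-beam CT grid; all geometry is
spacing-agnostic and the cohort pipeline plans at 1.0 mm. A seeded jitter
(uniform, ±0.5 mm per organ) emulates subject-to-subject contour
variation across a five-subject cohort; it is a stand-in convention, not a
measured variability model. What the phantom does **not** emulate —
realistic murine anatomy, CBCT noise, HU calibration, breathing motion —
bounds what passing tests mean: they validate the planning machinery and
the direction of the dosimetric contrast, not absolute organ doses in real
mice.

```{r}
library(soctmi)
ph <- generate_phantom(phantom_config(spacing = 1.0, seed = 2))
print(ph)
```

## The kV dose engine

The paper-grade engines for this problem are convolution/superposition
codes with poly-energetic kernels. `soctmi` uses a deliberately simpler,
closed-form-testable model: mono-energetic primary ray tracing at the
beam's effective energy (78.8 keV) plus an isotropic Gaussian lateral
kernel. The dose per unit weight of beamlet \((i,j)\) at a voxel \(v\) is

\[
d(v) \;=\; C \left(\frac{\mathrm{SID}}{s(v)}\right)^{2}
\exp\!\big(-\mu_w\, \rho_{\mathrm{rad}}(v)\big)\; f_{\mathrm{med}}(v)\;
\frac{b^{2}}{2\pi\sigma^{2}}
\exp\!\left(-\frac{r_{ij}(v)^{2}}{2\sigma^{2}}\right),
\]

where \(s(v)\) is depth along the field axis, \(\rho_{\mathrm{rad}}\) the
exact Siddon line integral of density from the source to the voxel
(g/cm²), \(\mu_w = 0.1835\) cm²/g the water mass attenuation coefficient
at 78.8 keV (standard tables), \(f_{\mathrm{med}}\) a per-medium
dose-to-medium enhancement (soft tissue 1.0, lung 1.0, bone 2.8 — the
bone value is a configuration choice that makes bone absorb well over
250% of the soft-tissue dose, as kV dosimetry does), and
\(r_{ij}(v)\) the distance, *measured in the isocenter plane after
back-projecting the voxel along its ray*, from the beamlet center.
Parameterising the kernel in the isocenter plane makes the open-field
lattice sum equal one independent of depth, so superposition of beamlet
columns reproduces the open-field dose and a single beamlet in vacuum
falls off as pure inverse square — both are tested.

Numerical choices: beamlets are 1 × 1 mm at the isocenter
(source-isocenter distance 305.4 mm, maximum field side 120 mm); the
kernel σ is 0.8 mm, truncated at 3.5 σ; influence entries below 1e-4 of
their column maximum are dropped (the superposition identity is preserved
to 0.5%); the absolute calibration \(C\) is conventional (1 Gy per unit
weight at the isocenter, unattenuated) since every reported metric is a
percentage of prescription. The engine is intentionally *not* a Monte
Carlo or superposition code: scatter buildup, spectral hardening and
electron disequilibrium are out of scope, and its 2% accuracy statements
refer to its own closed forms.

## Inverse planning

The optimizer minimizes, over nonnegative per-field fluence maps \(x\),

\[
\sum_s \frac{w_s}{|V_s|} \sum_{v \in V_s} \big(\text{one-sided residual}_s(Dx)_v\big)^2
\;+\; \lambda \sum_f \mathrm{TV}(x_f),
\]

with an underdose penalty \((p - d)_+^2\) for the target at the
prescription \(p\) = 12 Gy and overdose penalties \((d - g_s)_+^2\) for
the organs at risk (goal 0) and for soft tissue generally. The target
also carries a weak overdose term above 110% of prescription: a pure
underdose objective is indifferent to arbitrarily hot targets and, with
bone enhancement in the influence matrix, produces degenerate
homogeneity; the weak cap restores a well-posed solution. Default weights
(target underdose 100, target overdose 10, lungs/kidneys 10,
liver/heart/bowel 5, body 2) were chosen once as a sensible clinical-style
weighting; the published weighting for this problem is not available, so
these defaults reproduce orderings, not absolute organ doses.

\(\mathrm{TV}\) is the anisotropic total variation along the two leaf
axes of each field — the regularizer that drives fluence maps towards
piecewise-constant, rectangle-friendly structure. Its proximal map is
applied as exact 1-D proximal steps (Condat's direct algorithm,
`prox_tv1d()`) along rows then columns, then clamped at zero
(`prox_tv_row_col()`); the row/column alternation is an approximation of
the joint 2-D prox, standard and adequate here because the FISTA driver
accepts a candidate only if the full objective decreases. λ defaults to
0.05 × the sup-norm of the gradient at zero fluence so the
regularization scale follows the problem scale.

FISTA details: cold start at zero, step from a power-iteration Lipschitz
bound (with 5% headroom), monotone safeguard (momentum restart, then step
backtracking, on any objective increase — hence nonincreasing traces by
construction), convergence when the relative objective change stays below
1e-6 for 10 iterations, iteration cap 400 for cohort runs (2000 for
analyses that need tight convergence). Hitting the cap flags the plan but
is not an error.

## Rectangular aperture decomposition

Each optimized fluence map is peeled greedily into weighted rectangles
(`decompose_rectangles()`): at every step the rectangle maximizing
(minimum residual over the rectangle) × area — the largest possible L1
reduction whose weight keeps the residual nonnegative — is subtracted.
Ties prefer the larger area, then the smallest row-major origin, making
the decomposition deterministic. Peeling stops at a relative L1 residual
of 0.02 or a budget of 128 rectangles per field. Weights are continuous
(fluence-modulated delivery). Rectangle counts are emergent: on the
synthetic phantom a field typically needs on the order of ten rectangles,
fewer than a real mouse's anatomy demands, because analytic organs make
smoother fluence maps. The delivered dose is recomputed from the
rectangle-reconstructed fluence, and the delivered plan is rescaled so
the target median equals the prescription (`normalize = "ptv_median"`),
which makes the organ percentages comparable across plans.

## The parallel-opposed baseline

`auto_place_regions()` partitions the target's cranio-caudal extent into
contiguous slabs whose lengths equal the chosen collimator sizes, so
abutting field edges coincide exactly at the slab boundaries (field
matching). For a full mouse it uses the canonical seven-region template
(head 20 mm; four 10 mm spine slabs; femurs and tibias 20 mm each); small
targets fall back to a greedy tiling that picks, per slab, the smallest
of the five fixed apertures (40/20/10 mm squares, 10/5 mm circles)
covering the slab's target cross-section. Head and spine slabs get
lateral opposed pairs (gantry 90°/270°), limb slabs dorso-ventral pairs
(0°/180°) — the axis convention mirrors the published arrangement
qualitatively; the exact per-region axes of the original are not fully
legible and are a documented convention here. Each region's weight is set
so the dose at its normalization point (the slab's target centroid; the
original names per-region normalization points without placing them)
equals the prescription. Beam divergence makes perpendicular limb beams
cross the lateral spine beams beyond the matched planes, producing the
junction hot spots that `junction_report()` lists as 26-connected
clusters above 110% of prescription (the threshold is a convention; the
original reports hot spots without a number).

## Analytics conventions

* median = 50th percentile with midpoint interpolation for even counts;
* cohort SD is the sample SD (n−1) — required to reproduce the reference
  table's SD row (the population SD gives 8.8 instead of 9.8 for the
  bowel column);
* report rounding is one decimal, half away from zero;
* "reduction by X% of prescription" is `100 − mean(conformal medians)`;
* integral dose is the volume-weighted mean dose over body minus skeleton
  minus spleen, as % of prescription (mass weighting is off: at these
  densities it changes little and the reference quantity is volumetric).

The bundled five-subject reference table carries two documented
transcription notes: the garbled m1/heart baseline cell is read as 11.1
(the only value consistent with the printed column average of 10.0), and
the heart reduction's published "± 11.3" conflicts with the table's own
SD of 6.9 — the package reproduces the table SD. Two published paired
reductions (kidneys 80.6, liver 15.4) are not derivable from the printed
per-subject values (which give 80.0 and 15.5); the package reports the
recomputed values.

## Problem sizes and determinism

The cohort pipeline (`run_pipeline()`) plans five subjects at 1.0 mm
grid spacing (~25k body voxels, ~7k beamlets across seven fields, ~5M
influence nonzeros per subject), a size chosen so a full cohort runs in a
few minutes on a laptop core while preserving every geometric feature the
comparison depends on. Subject seeds are `master_seed + 1 …
master_seed + cohort`; every stage is a pure function of its
configuration and seed, so rerunning a configuration reproduces metric
CSVs byte-for-byte.

## Known limitations

* The dose engine is a primary + Gaussian-kernel model: no scatter
  buildup, no spectra, no electron transport.
* The phantom is analytic; absolute organ percentages depend on real
  anatomy and on the original study's unpublished constraint weights, so
  only orderings and the printed-table statistics are asserted
  quantitatively.
* The statistical test behind the published p-values is not stated in the
  source material; `compare_plans()` defaults to a paired t-test and
  exposes a Wilcoxon option, and the package does not target those
  p-values.
* Leaf-travel deliverability, collimator transmission and treatment-time
  modelling are out of scope.
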