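---
title: "Methods: template-based knee compartment mechanics and degeneration forecasting"
author: "kneedegen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: template-based knee compartment mechanics and degeneration forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kneedegen)
```

## What the package models

`kneedegen` forecasts knee osteoarthritis (OA) progression from simple
baseline information. The premise is mechanical: cartilage whose collagen
network is chronically stressed beyond an age-dependent tensile strength
degenerates, and the amount of over-stressed tissue at baseline should
separate knees that later reach different Kellgren-Lawrence (KL) severity
grades. The pipeline has five stages:

1. **Geometry.** A layered hexahedral template of each tibiofemoral
   compartment (femoral + tibial cartilage) is scaled to a subject's
   anatomy from four MRI-style measurements: anterior-posterior condyle
   extent (X scaling), intercondylar distance (Z scaling), joint space
   (thickness scaling) and the femoral fraction of the joint space.
2. **Loading.** A fixed, normalized stance-phase joint contact force (JCF)
   shape paired with a fixed flexion trajectory is scaled to subject peaks
   under three schemes: even 50/50 compartment sharing of a body-weight
   peak; neural-network (NN) load sharing with body-weight peaks; NN load
   sharing and peaks.
3. **Mechanics.** Per-element maximum principal solid stress over stance
   from an instantaneous-incompressible elastic-foundation contact
   surrogate (below).
4. **Degeneration.** Elements whose stress envelope exceeds an
   age-dependent threshold are summed (volume) over the central joint
   region and normalized by the central reference volume.
5. **Classification.** Degenerated-volume fractions are scored against KL
   groups at follow-up (KL 0-1 / KL 2 / KL 3-4) with Mann-Whitney AUC and
   DeLong inference, plus a nonparametric battery (Kruskal-Wallis,
   Wilcoxon signed rank, Friedman, Bonferroni).

## The contact surrogate and its assumptions

A full biphasic fibril-reinforced finite-element contact solve is out of
scope; it is replaced by a documented column (elastic foundation)
surrogate. The justification is the same one used to choose
sliding-elastic contact in full models: over the ~1 s of a stance phase,
fluid exchange in cartilage is negligible, so the instantaneous,
effectively incompressible response dominates the solid stress.

Each footprint cell of the tibial plateau defines an independent vertical
column carrying both cartilage layers in series. For one tissue at
compressive strain $\varepsilon$ (axial stretch
$\lambda = 1-\varepsilon$), incompressibility gives the in-plane stretch
$\lambda_t = \lambda^{-1/2}$. The collagen fibrils see the Green-Lagrange
strain $E_f = (\lambda_t^2 - 1)/2$ and respond in tension only with
power laws $\sigma_p = \xi_{fp} E_f^{\beta_{fp}}$ (primary) and
$\sigma_s = \xi_{fs} E_f^{\beta_{fs}}$ (secondary). The non-fibrillar
matrix contributes shear $\mu = E_{nf}/(3(1+\nu_{nf}))$ with in-plane
deviatoric stress $\sigma_m = \mu(\lambda_t^2 - \lambda^2)$. The surface
maximum principal stress is $\sigma_I = \sigma_p + \sigma_s + \sigma_m$
and the column pressure is
$p = \mu(\lambda^{-1} - \lambda^2) + \sigma_p + \sigma_s$. Note that,
because $\lambda_t^2 = \lambda^{-1}$, these formulas make
$\sigma_I \equiv p$ at the surface — the fibril network carries
essentially the whole contact pressure, which is the intended behaviour
of the instantaneous fibril-reinforced response.

The femoral and tibial sub-columns share the column strain so that their
pressures match (a 1-D root find; the softer tibial matrix and fibrils
absorb the larger strain share). Frame equilibrium finds the rigid axial
approach $\delta$ such that $\sum_i p_i(\varepsilon_i(\delta)) a_i = F$
to a relative residual below $10^{-6}$, with
$\varepsilon_i = \max(0, (\delta - g_i)/T)$ for gap $g_i$ and total
thickness $T$, and a total-strain cap of 0.6 beyond which the column
response saturates (flagged; a frame whose force exceeds the saturated
capacity errors out and the pipeline logs that knee as a failure).

Depth variation of the collagen arcade is reduced to a fixed weight
profile: the superficial/middle/deep thirds of each tissue scale the
surface stress by 1.0/0.5/0.25 (configurable). Permeability constants
(`kappa0`, `M_perm`, `phi0`) are carried in the material set solely for
the FEBio-dialect deck exporter; the instantaneous surrogate involves no
fluid flow by construction.

What the surrogate does *not* claim: quantitative agreement with full FE
stress fields. It preserves the orderings the forecasting statistic needs
(stress monotone in force; medial/lateral contrast following load sharing
and congruence) and is bit-for-bit reproducible from the closed forms
above.

## Geometry choices

The distributed template of the original method is not available, so the
package builds a parametric stand-in: an elliptic-paraboloid condyle cap
over a gently concave (medial) or flat (lateral) plateau, with uniform
per-tissue thickness. Template measurements default to the cohort
medians (ICD 40.6 mm, A-P 53.05/62.59 mm, JS 4.79/5.38 mm, femoral
fractions 0.55/0.40), so a median subject is a near-identity scaling.
The lateral compartment gets tighter condyle radii over a flatter
plateau, encoding its lower congruence. Condyle radii (40/30 mm medial,
32/24 mm lateral; tibial dish 120/80 mm medial) are in the range of
adult knee anatomy and were fixed once at design time.

Axis convention: X anterior-posterior, Y axial (the loading direction),
Z medial-lateral. The anatomic scaling sentence of the source method
assigns ICD to "Y", but its loading sentence fixes Y as axial, so ICD
cannot scale Y; the package applies the ICD ratio mediolaterally (Z).

Thickness offsets are applied **vertically** (along Y) from the articular
surface anchors for both tissues and both scaling modes, rather than
along local surface normals for the femur. For the shallow condyle cap
the normal deviates from vertical by only a few degrees, and the vertical
convention buys three exact invariants: identity scaling is exact;
fixed-ratio volume scales exactly by
`ap_ratio * icd_ratio * js_ratio`; and the two thickness modes produce
coordinate-identical meshes whenever the subject's femoral fraction
equals the template's. It also matches the vertical-gap column contact
model exactly.

Flexion is a rotation of the femoral articular surface about Z through
the surface centroid (the source does not state a rotation center); the
sign convention moves the closest-approach point posteriorly for
positive flexion. The central region used for the degenerated-volume
reference is the middle third of the plateau's A-P extent
(`central_fraction = 1/3`), mirroring MOAKS-style partitioning.

## Loading choices

The reference JCF shape is analytic — two smooth humps at ~25% and ~75%
stance with a midstance trough at ~0.6 of peak, normalized to max 1 on a
51-point grid (every 2%) — and the flexion trajectory peaks at ~15
degrees near 15% stance with ~5 degrees at midstance, rising toward
toe-off. Both are configurable from CSV; the defaults are placeholders
with the qualitative features of instrumented-implant and gait-lab data.
The peak body-weight multiplier defaults to 2.6 BW, in line with
instrumented-implant walking peaks; the source cites such data without
printing a number.

Load shares are **not** renormalized to sum to one: they are defined as
ratios of independently predicted compartment maxima, which occur at
different gait instants. A configurable cartilage-contact fraction
(default 1.0) can down-scale compartment forces to emulate meniscal load
bearing, which the source handles inside its reference peaks.

The peak predictor is a single-hidden-layer tanh network (width 10)
trained by full-batch BFGS on standardized inputs/outputs with a small L2
penalty — deterministic given the seed. Because the networks of the
original studies and their training data are unavailable, targets come
from a synthetic musculoskeletal surrogate: total peak (BW) rises with
walking speed and falls slightly with mass, and varus alignment shifts
load medially (about +2.2% medial share per degree). Additive noise is
calibrated per output as `sd(signal) * sqrt(1/r^2 - 1)` so the
population correlation ceilings mirror the published network accuracies
(medial 0.61, lateral 0.67, total 0.80).

## The synthetic cohort: what it emulates and what it does not

`generate_cohort()` draws per-knee records whose medians and IQRs match
the published 97-knee cohort summaries (71% female; log-normal marginals
for lengths and mass, truncated normals for age, speed, alignment and
the femoral fractions; height-mass Gaussian copula with rho = 0.5 — the
source gives no joint distribution). KL groups at follow-up fill the
29/37/31 split by ranking a latent score,
`effect_size * standardize(peak medial load / medial joint space) +
N(0,1)`. This link is an artifact construct: the original study
*observes* outcomes, it does not generate them. `effect_size = 1.5`
(default) makes the mechanics-KL association recoverable end-to-end;
`effect_size = 0` severs it, which is the null used to check that the
pipeline does not manufacture signal.

A green planted-signal test therefore establishes that the pipeline
recovers a known mechanical association through all of its stages — not
that the association exists in real knees, and not that real-data AUCs
(reported around 0.70 for the best variant) are reproduced. Real
radiographs, segmentation error, meniscal pathology and the true joint
distribution of anatomy are all outside the generator.

## Degeneration statistic

"Exceeding the threshold during the stance phase" is read as exceedance
at any stance frame (the per-element envelope), consistent with
reporting a single volume per simulation. The reference volume is the
central-region cartilage of *both* tissues per compartment, so femoral
and tibial fractions add up to the compartment fraction (a per-tissue
reference is available behind a flag). Thresholds use baseline age. The
two threshold families are implemented exactly as printed: the piecewise
monotone-tension curve (30 MPa up to age 30 down to 6.8 MPa above 75)
and the cyclic-fatigue relation `25.4 - 0.15 Age - 1.65 log10(N)` with
N = 1e5/1e6/1e7; the fatigue relation errors out when exhausted
(non-positive).

## Numerical choices

* Frame equilibrium: bracketed root find on the axial approach;
  residual tolerance 1e-6 relative, typically ~1e-12 in practice.
* Column response: tabulated at 161 strain points with vectorized
  bisection for the series partition (60 iterations), linearly
  interpolated; tables are cached per thickness fraction and material
  set, which makes fixed-ratio cohorts share one table.
* Strain cap 0.6 (saturating, flagged); per-tissue strains in the
  partition are bounded at 0.95 to keep stretches positive.
* Mesh validity is checked through signed 5-tetrahedron volumes and
  corner Jacobians; the 5-tet decomposition makes volumes exactly linear
  in the vertical thickness scaling, which is what the exact-covariance
  test exploits.
* AUC ties take half credit (midranks); DeLong variance uses placement
  values; Wilcoxon/Kruskal-Wallis/Friedman delegate to `stats::` with
  the normal approximation for ties.

## Known limitations

* The surrogate has no poroelastic time dependence, no friction, no
  menisci, and no bone compliance; absolute stress magnitudes are
  indicative only.
* The parametric template does not reproduce the element counts or
  aspect-ratio statistics of the segmented original.
* The JSW tool measures programmatic contours, not images; the "central
  point" of a condyle is ambiguous in the source and defaults to the ROI
  z-midpoint (lowest-point alternative behind a flag).
* Whether left/right knees should be mirrored into one frame is
  unstated in the source; the generator records `knee_side` but geometry
  treats all knees in one canonical frame.
* Real-data headline numbers (AUC grids, medial/lateral degeneration
  ratios, JSN regressions) require the gated observational cohort and
  are deliberately not asserted anywhere in the tests.
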