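---
title: "Disuse remodeling of the implanted femur: model and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disuse remodeling of the implanted femur: model and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

osteosim simulates how the proximal femur loses bone after a total hip
arthroplasty (THA), and how an electrostatic stimulation protocol can slow
that loss. This vignette is the package's own account of the model, its
parameters, the numerical choices, and what the synthetic fixtures do and
do not establish.

## The physical picture

A femoral stem is far stiffer than the bone it replaces (titanium-class
alloys around 110 GPa against at most a few GPa for bone). After
implantation the stem carries most of the joint load, so the surrounding
bone — above all the femoral neck — sees much lower stress than it did
pre-operatively. Remodeling interprets chronic under-loading as a signal
to resorb: basic multicellular units (BMUs) are activated on internal bone
surfaces, each resorbing a packet of bone and refilling it only after a
long delay. Under sustained disuse the resorbing population outruns the
refilling one and apparent density falls, which in turn softens the bone
and deepens the shielding. Electrical stimulation is modeled
phenomenologically as a local suppressor of BMU activation, strongest
where the electrostatic potential is highest.

## Model components

### Material mapping

Bone elements carry an apparent density `rho` (g/cm^3) obtained from a
synthetic CT number by a linear ramp between model-wide bounds
(`hu_min -> rho_a`, `hu_max -> rho_b`), then quantized once to `n_bins`
discrete levels (default 50, the "material gradient"). Density couples to
porosity through `rho = (1 - P) * rho_0` and to stiffness through the
cubic law `E = 3790 * rho^3` (MPa). Both couplings are enforced after
every remodeling step, so the three per-element fields never drift apart.
The bounds `rho_a = 0.1`, `rho_b = rho_0 = 1.8` g/cm^3 are a standard
apparent-density range consistent with the cubic law's MPa/(g/cm^3)
calibration; they are configuration, not measured values. Elements at or
above 1.3 g/cm^3 are classified cortical, the rest cancellous; the split
only selects which BMU stage durations apply and is fixed at
initialization.

### Daily load cases and stimulus

Three daily conditions load the femur: standing (6000 cycles, joint force
2317 N at 24 degrees, abductor force 703 N at 28 degrees), hip abduction
(2000 cycles, 1158 N at -15 degrees, 351 N at -8 degrees) and hip
adduction (2000 cycles, 1548 N at 56 degrees, 468 N at 35 degrees).
Angles are measured from the proximal shaft axis in the coronal plane —
the frame is a documented package convention, since only magnitude and
angle are given. Forces are applied as uniform tractions over fixed
surface patches (point loads would produce singular stresses that corrupt
element-wise fields), and the distal cut plane is fully fixed.

Each solve yields a per-element von Mises stress; the daily stimulus is
the cycle-weighted power mean with exponent `m = 4`:

    Phi = (sum_j n_j * sigma_j^m)^(1/m)   [MPa]

The equilibrium stimulus `Phi0` is the same quantity evaluated on the
*intact* femur, element by element, mapped onto the implanted mesh by
nearest-centroid matching and floored at 1e-6 MPa so the ratio `Phi/Phi0`
stays defined in essentially unloaded regions.

### BMU population kinetics

Disuse activation follows a sigmoid in the stimulus ratio,

    fa = fa_max / (1 + exp((Phi/Phi0 - 0.5) / 0.1)),

with `fa_max = 0.1` BMUs/(mm^3 day). At the equilibrium ratio of 1 this
gives `fa0 = 0.1/(1 + e^5) ~ 6.7e-4`; under total disuse it saturates
near `fa_max`. The typeset form of this sigmoid admits more than one
reading; the package uses the standard disuse form above, which is the
only one consistent with "less loading, more activation" and with the
role of the two shape factors.

Activation only happens on internal surfaces, so `fa` is weighted by the
specific surface, a quintic in porosity
(`Sr = 32.1 P - 93.9 P^2 + 134 P^3 - 101 P^4 + 28.8 P^5`, mm^2/mm^3) that
vanishes for both solid and fully porous tissue. Each day the product
`fa_eff * Sr(P)` is appended to a per-element ring buffer of length
`T_R + T_I + T_F` days — the full BMU lifetime for that bone class
(cortical 24/8/64 days, cancellous 60/57/197 days). The two population
integrals are windowed sums over this buffer:

* `N_R`: the newest `T_R` entries — BMUs currently resorbing;
* `N_F`: the oldest `T_F` entries — BMUs that have passed resorption and
  reversal and are refilling.

With this discretization a change in activation reaches the filling pool
exactly `T_R + T_I` days after it enters the resorbing pool, and a
constant history gives `N_R = c T_R`, `N_F = c T_F` exactly.

Porosity then advances by forward Euler with a one-day step:

    dP/dt = Q_R * N_R - Q_F * N_F

`Q_R` is the per-BMU resorption rate from the simplified BMU geometry: a
cylindrical tunnel of diameter `d_o = 0.2` mm advancing at
`v = 0.01` mm/day in cortical bone (`Q_R = pi d_o^2 v / 4`), and a
semi-elliptic surface groove of width `d_BMU = 0.65` mm and depth
`d_e = 0.05` mm in cancellous bone (`Q_R = pi d_e d_BMU v / 4`). The
filling rate is closed by the equilibrium balance `Q_F = Q_R T_R / T_F`,
the unique choice for which a constant history produces exactly zero net
change — the pre-operative skeleton is assumed to be at remodeling
equilibrium, and the history buffers are pre-filled with `fa0 * Sr(P0)`
accordingly. Porosity is clamped to [0.01, 0.99] so stiffness stays
strictly positive.

One unit inconsistency is inherited knowingly: `fa_max` is quoted in
BMUs/(mm^3 day) yet is multiplied by a specific surface in mm^2/mm^3. The
package uses the printed numeric values and treats `fa * Sr` as a BMU
activation density per day rather than rescaling either quantity.

### Electrostatics and modulation

Bone is a weakly anisotropic dielectric: `beta11 = 88.54e-12` F/m
transverse, `beta33 = 106.248e-12` F/m along the shaft axis. A single
static solve of `div(beta grad phi) = 0` is performed per protocol, with
32 V on a circumferential band of the neck surface and 0 V on the distal
cut, zero-flux elsewhere. The potential is averaged per element and
rescaled to [0, 1] (`phi_hat`), so the electrode region has influence 1
and the ground 0 regardless of the drive voltage. This is deliberately a
permittivity boundary-value problem, not a conduction problem — the model
defines the stimulation field that way, and the package implements
exactly that while noting the physical ambiguity. The implant is assigned
the bone dielectric by default because its electrical role is not part of
the model.

Inside the stimulation window (default start day 101; durations 50, 100,
150 days or open-ended) the activation frequency is suppressed in
proportion to the local normalized potential:

    fa_eff = fa * (1 - A * phi_hat),   A in {0, 0.3, 0.5, 0.7}.

The suppression enters `N_R` and `N_F` through the one shared history.
This single-channel reduction reproduces all the qualitative behaviour of
interest: losses slow during stimulation; density can transiently *rise*
at high amplitude because `N_R` responds `T_R + T_I` days before the
filling pool drains; and the density-change rate returns negative once
stimulation stops. Whether stimulation should act asymmetrically on
resorption versus filling is an open biological question; the symmetric
choice is a documented package decision, not a claim about mechanism.

A corollary worth knowing: because suppressed resorption re-emerges as
suppressed *filling* `T_R + T_I` days later, a short window can overshoot
— in the shipped fixtures a 50-day window ends the 300-day run a few
1e-5 g/cm^3 *below* the unstimulated trajectory, while the 50/100/150-day
windows order monotonically among themselves. This rebound is a property
of the delay structure, not a numerical artifact.

## Synthetic fixtures

No patient geometry ships with the package, so all tests run on two kinds
of generated meshes.

*Verification fixtures* are structured boxes split 6 tetrahedra per cell
(Kuhn split, conforming across cells), at linear (tet4) or quadratic
(tet10) order. They carry exact reference solutions: constant-stress
patch states, the Euler-Bernoulli cantilever, the linear electrostatic
slab and the two-layer voltage divider.

*The femur fixture* is a parametric proximal femur — vertical shaft,
angled neck (default 130-degree neck-shaft angle), spherical head —
meshed by clipping a structured grid to the implicit solid, in the spirit
of voxel-based micro-FE models. Selection works on whole cells and keeps
the face-connected component anchored at the base, so no sub-body is
attached through a single edge or vertex (which would carry rigid
zero-energy modes). The boundary is closed in the cycle sense — every
boundary edge borders an even number of boundary faces — which is the
appropriate watertightness notion for a voxelized surface. The implanted
variant removes the head and labels a stem region (neck axis plus
medullary canal) as implant on the *same* grid, so the shared bone
elements of the two variants coincide exactly and the nearest-centroid
matching (implemented generally, with a distance cap of 25% of the local
element size) is exact on the fixtures. The synthetic HU field gives the
fixture a dense cortical shell, a mid-density cancellous interior and a
low-density marrow canal, with optional clipped Gaussian noise.

What the fixtures do *not* emulate: real cortical geometry and thickness
variation, trabecular anisotropy, patient-specific load directions, the
actual stem shape, or bonded-interface micromechanics. Passing the
acceptance suite therefore establishes that the *model and its numerics*
behave as published — shielding concentrated in the neck, monotone dose
response, the delay structure — not that the package reproduces any
patient's densitometry. The published patient-specific percentages
(77.5%/43%/86% of elements shielded; 0.17 g/cm^3 maximum neck loss)
depend on CT geometry that is not deposited and are treated as
qualitative anchors only.

## Numerical choices

* Elasticity and electrostatics are assembled element-wise in compiled
  code and solved by sparse Cholesky factorization; one factorization is
  shared by all load cases of a day. Solver residuals are checked at
  1e-8 relative.
* Element stress is the centroid value for tet4 and the volume-averaged
  quadrature value for tet10 (4-point rule, exact for the quadratic
  stiffness integrand).
* Uniform tractions use consistent nodal loads: A/3 per corner on linear
  faces; A/3 per midside node and zero at corners on quadratic faces.
* The day loop re-solves the stress problem every `fe_update_interval`
  days (default 1; the shipped studies use 5) and reuses the last stress
  field in between. Time integration is forward Euler with a 1-day step,
  matching the day-resolution of the stage durations.
* Stress-ratio histograms use width-0.1 bins that are closed on the
  right, with the first bin closed at zero, so a ratio of exactly 1
  counts as shielded — this makes the "0 to 1" shielded fraction equal
  the sum of the first ten bins with no edge ambiguity. Elements whose
  intact stress is below 1e-6 MPa are excluded from ratios and counted
  separately.
* Ring-buffer window sums run oldest-to-newest so they agree bit for bit
  with a chronological brute-force sum.

## Problem sizes

The shipped studies balance resolution against runtime as a package
choice: homeostasis runs on a ~1000-element fixture for 300 days; the
stimulation grid (four amplitudes, three window durations) runs on a
~15000-element intact / ~11000-element implanted pair for 300 days at a
5-day stress-update cadence; verification problems use a few hundred
elements where the reference solutions are exact. At these sizes the full
acceptance computation completes in minutes on one CPU.

## Package shape

Meshes and solver state are plain S3 lists, as is usual for FE codes;
everything a user analyses — material fields, time series, histograms,
reports — is a tibble, and result objects provide `tidy()`, `glance()`
and `autoplot()` methods so they drop into dplyr/ggplot2 pipelines.

## Known limitations

* Isotropic linear elasticity with a bonded bone-implant interface; no
  contact, micromotion, or fatigue.
* The electrostatic layer is static and permittivity-based; no currents,
  pulsing, or piezoelectric coupling.
* Bone classification is fixed at initialization; an element that
  densifies past the cortical threshold keeps cancellous kinetics.
* The ES channel is symmetric between resorption and filling (see the
  rebound note above).
* Voxelized fixture surfaces are stair-stepped; surface-stress values on
  the femur fixture are mesh-convergent only in the average, which is why
  element-wise ratios are always aggregated before interpretation.
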