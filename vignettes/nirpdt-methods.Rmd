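---
title: "Methods: voxel dosimetry of NIR photodynamic therapy with upconversion photosensitizers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel dosimetry of NIR photodynamic therapy with upconversion photosensitizers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirpdt)
```

## The problem

Ductal carcinoma in situ (DCIS) is confined to the milk ducts and typically
sits 15--25 mm below the skin. Photodynamic therapy (PDT) could treat it
non-invasively, but conventional photosensitizers are excited by visible
light, which barely penetrates breast tissue. Upconversion constructs
(UCQRs: an upconversion nanoparticle decorated with quantum dots and
carrying Rose Bengal) absorb near-infrared light at 808 nm --- inside the
tissue optical window --- and convert it internally to 540-nm excitation of
the photosensitizer. `nirpdt` implements a complete in-silico trial of this
therapy on voxelized breast phantoms: how much 808-nm light reaches a
duct-confined tumor, how much singlet-oxygen-generating dose one
irradiation session deposits, and how many identical sessions are needed to
treat the whole tumor.

## Pipeline overview

1. **Phantom** --- a `labeled_volume`: a 3D grid of tissue labels
   (air/skin/fat/duct, plus tumor after embedding) at an isotropic pitch,
   0.33 mm by default. Phantoms are loaded from NIfTI files or PNG slice
   stacks, or generated synthetically.
2. **Density & classification** --- glandular density is the duct fraction
   of soft tissue, `n_duct / (n_duct + n_fat)`, computed *before* tumor
   embedding and frozen. Raw CT-derived densities are multiplied by 2.5
   (capped at 100%) before BI-RADS-style binning, because raw voxel
   densities of CT label maps run well below the mammographic densities the
   bins were calibrated on.
3. **Tumor embedding** --- a 7-mm sphere is voxelized by center inclusion
   and placed entirely within duct voxels at 15--25 mm depth; among
   admissible sites the shallowest is chosen.
4. **Light transport** --- weighted-packet Monte Carlo at 808 nm scores the
   per-voxel fluence rate (mW/cm^2) under a 330 mW/cm^2 collimated field
   directed along the body axis.
5. **Dose** --- the UCQR cascade converts tumor-voxel fluence into a
   per-session photodynamic dose (photons/cm^3).
6. **Planning** --- voxels die once accumulated dose reaches
   8.6e17 photons/cm^3; the treatment is complete when every tumor voxel
   has died.

## The energy-transfer cascade

Three sequential transfers move energy from the 808-nm photons to the
photosensitizer:

* **ET1 = 16.3%** --- quantum dot to Yb ions (resonance energy transfer);
* **ET2 = f540 x p_multi** --- Yb to Er upconversion: 50% of the
  transferred energy follows the 540-nm emission pathway that excites Rose
  Bengal, gated by the probability `p_multi` that two or more photons are
  absorbed within the excited-state lifetime. That probability is not
  experimentally accessible, so the canonical study sweeps it over
  {0.2, 0.4, 0.6, 0.8, 1.0};
* **ET3 = 75%** --- Er to Rose Bengal.

The overall efficiency `ETE = ET1 x ET2 x ET3` then spans 1.2%--6.1% over
the `p_multi` grid (one-decimal display rounding, half-up; full precision is
used in every computation):

```{r}
round_half_up(100 * ete_grid(), 1)
```

## The dose model

The per-session photodynamic dose in a tumor voxel is

```
PD = mu_a_UCQR * phi * ETE * gamma * t_session / E540   [photons/cm^3]
```

with `phi` the local fluence rate (W/cm^2 after unit conversion),
`mu_a_UCQR = 0.38 cm^-1` the UCQR absorption coefficient at the 75 mg/kg
intratumoral concentration, `gamma` the singlet-oxygen quantum yield and
`E540 = hc / 540 nm` computed from physical constants. A dimensional note:
fluence divided by photon energy alone yields photons per *area*; the
stated threshold (8.6e17 photons/cm^3) and the accompanying description
("the fluence absorbed by UCQRs in each voxel") are volumetric, so the
absorbed power density `mu_a_UCQR * phi` is the quantity converted to
540-nm photon equivalents. This is the standard Farrell-style threshold
dose construction, and it is the single most consequential interpretation
made in this package; it is therefore exposed explicitly as the
`mu_a_ucqr_cm` parameter of `dose_params()`.

`gamma` is not a measured constant of this construct. The default 0.75 is
the Rose Bengal literature value; every dose-dependent output carries its
`dose_params` provenance so a different yield can be swept without
re-running transport.

Oxygen is assumed non-limiting throughout: no oxygen-depletion or
photobleaching kinetics are modeled, so doses in chronically hypoxic
tumors would be overestimated.

## Monte Carlo transport

The engine is a voxel Monte Carlo with variance-reduced weighted packets
(the scheme used by the MCX family of codes):

* packets launch uniformly over the beam field on the entry face, direction
  along the body axis; specular Fresnel reflection is applied at the
  ambient-air entry;
* scattering interactions are sampled from `mu_s`; along every traversed
  segment the packet deposits `W (1 - exp(-mu_a l))` into the voxel it
  crosses, so absorption is continuous and the scored fluence follows
  `phi = A / (mu_a V)` exactly. With `mu_s = 0` the transport reduces
  analytically to Beer--Lambert attenuation, which the test suite uses as a
  closed-form oracle;
* scattering angles are Henyey--Greenstein (inverse CDF) with per-tissue
  anisotropy `g = 0.9`;
* refractive-index mismatches at interior voxel faces trigger unpolarized
  Fresnel reflection/refraction. The per-tissue indices differ (skin 1.37,
  duct 1.42, fat/tumor 1.45), so these interfaces matter; a flag disables
  them for the Beer--Lambert validation;
* Russian roulette terminates packets below weight 1e-4 with survival
  probability 0.1. The net weight the roulette creates or destroys is folded
  into the absorbed ledger entry, so every run satisfies
  `launched = absorbed + reflected + transmitted` to 1e-6 exactly, not just
  in expectation;
* each packet owns an RNG substream (xoshiro256+ seeded by splitmix64 from
  the run seed and the packet index), so results are bit-reproducible and
  independent of execution order.

Geometry is handled internally in voxel units with coefficients
pre-multiplied by the pitch; user-facing units are mm for geometry, cm^-1
for optical coefficients and mW/cm^2 for fluence.

Default packet counts are 1e6; the standard broad-field geometry on a
120^3 grid runs in well under a minute per phantom at that count on one
CPU core. Beam footprint defaults to the full entry face (broad-field
illumination); a disc field is available.

## The synthetic phantom generator

Real CT-derived phantom cohorts are distributed on request only, so the
package ships a seeded generator whose defaults define the study
conditions:

* **contour** --- a pendant hemiellipsoid (prone geometry) with its apex
  facing the beam; the flat base abuts the chest-wall face of the grid and
  carries no skin;
* **skin** --- a closed shell of 1.5 mm default thickness (about the real
  breast skin thickness and >= 4 voxels at 0.33 mm pitch), carved with an
  exact Euclidean distance transform from the air interface, so no interior
  voxel touches air;
* **ducts** --- a thresholded Gaussian random field with a 4-mm correlation
  length, converted fat-to-duct from the highest field values down until the
  voxel-tally density equals the target exactly (the generator's density is
  exact by construction; the +-0.02 test tolerance covers discreteness);
* **host block** --- an optional solid duct cube (>= 9 mm) positioned so
  that the *shallowest* admissible 7-mm sphere sits exactly at the
  requested depth. This placement is computed from the voxel-center
  membership rule (block center at depth `host_depth + top_offset + slack`
  voxels below the apex skin), making the generator's depth a usable ground
  truth for embedding tests;
* **cohorts** --- densities drawn from a bin mixture concentrated below
  0.30 raw density (weights 84/46/17/3 over
  [0,0.1), [0.1,0.2), [0.2,0.3), [0.3,0.45)), the shape of the CT-derived
  cohort histograms this generator stands in for.

What the generator does **not** emulate: Cooper ligaments, vasculature,
chest-wall anatomy, realistic duct branching topology, or inter-patient
contour variability beyond the semi-axis parameters. Tests passing on
synthetic phantoms therefore validate the *pipeline machinery and physics*,
not anatomical realism: fluence heterogeneity across real glandular
structures will exceed what the smooth random-field texture produces.

## Embedding conventions

* Depth is measured along the beam axis from the *outer* skin surface (the
  air interface) to the upper face of the shallowest tumor voxel.
  "Distance to the skin" is ambiguous (outer vs inner surface, axial vs
  Euclidean); the outer-axial convention is chosen because irradiation dose
  and reported depth annotations reference the illuminated surface.
* Sphere membership is voxel-center inclusion (strictly inside the radius).
  The alternative any-overlap rule inflates the voxel count by a surface
  layer; center inclusion matches the analytic volume to 2% at the default
  pitch.
* The all-duct test uses an exact Euclidean distance transform of the
  non-duct mask: a sphere is entirely duct iff the nearest non-duct voxel
  center is at least one radius from the center. This is exact, and turns
  the candidate search into a thresholding operation.
* Tie-breaks: minimal depth first, then smallest lateral distance to the
  apex axis, then lexicographic voxel index. Deterministic by construction.

## Treatment planning

Sessions are identical --- optical properties do not change as voxels die
--- so dose accumulates linearly and a voxel needs
`ceiling(threshold / PD_session)` sessions. Reaching the threshold exactly
counts as death (the boundary case has measure zero in floating point; the
choice makes the integer arithmetic deterministic). Voxels with zero
session dose are reported as unreachable (`Inf`), never as a large
integer. Kill maps are nested across sessions by construction, and on
fluence fields that decay with depth the treated region grows monotonically
downward from the beam-facing tumor surface.

## Numerical and testing choices

* One-decimal report values round half-up (`round_half_up()`), matching the
  convention of the summary statistics the package reproduces.
* Bin edges for the density classes are half-open `[lo, hi)` with the top
  bin closed; adjusted density is capped at 100%. The bins are applied
  strictly: an adjusted density of 58% is heterogeneously dense, even
  though descriptions in the literature occasionally label mid-50s
  densities "scattered".
* Representative-phantom selection breaks ties by lowest id.
* Test problem sizes: unit tests run transports at 2e4--2e5 packets on
  grids up to 72 x 72 x 96; the end-to-end session-count study runs three
  120^3 phantoms (tumor depths 15/20/25 mm) at 1e6 packets each. These
  sizes keep the full suite around two minutes on one core while leaving
  Monte Carlo noise far below every asserted tolerance.
* The default `120^3` grid used in examples is a scaled version of the
  500^3 clinical-resolution grid; the 500^3 default remains available and
  is a configuration choice, not a limit of the implementation.

## Known limitations

* The excitation-intensity dependence of the Yb-Er upconversion step is not
  modeled (ET2 is constant per run), which overestimates dose in deep tumor
  voxels relative to shallow ones.
* No oxygen kinetics, no photobleaching, no thermal effects.
* Tumors are spheres; non-spherical and multifocal disease is out of scope.
* Er emission at 410/660/1540 nm is not propagated (it does not excite the
  photosensitizer), and the 540-nm pathway transfers by resonance without
  propagating, so no secondary transport is run.
* The fluence-to-dose conversion interprets the threshold volumetrically
  via `mu_a_UCQR` as discussed above; results scale trivially if a
  different convention is preferred.
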