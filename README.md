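# nirpdt

Virtual trials of near-infrared photodynamic therapy (NIR-PDT) in voxel
breast phantoms.

Ductal carcinoma in situ grows inside the milk ducts, typically 15–25 mm
below the skin — too deep for photodynamic therapy with visible-light
photosensitizers. Upconversion constructs (**UCQRs**: an upconversion
nanoparticle carrying quantum dots and Rose Bengal) absorb 808-nm light in
the tissue optical window and convert it internally to 540-nm excitation of
the photosensitizer. `nirpdt` is for biomedical-optics and PDT-dosimetry
researchers who want to ask, in silico: *how much 808-nm light reaches a
duct-confined tumor, how much singlet-oxygen dose does one irradiation
session deposit, and how many sessions does complete treatment take?*

The package implements the whole pipeline:

- **Phantoms** — labeled voxel volumes (air/skin/fat/duct/tumor) at 0.33 mm
  pitch, loaded from NIfTI or PNG slice stacks, or produced by a seeded
  synthetic generator (pendant hemiellipsoid breast, closed skin shell,
  Gaussian-random-field duct texture at an exact target density, and a
  guaranteed duct "host" region for reproducible embedding).
- **Density & classification** — glandular density
  `n_duct / (n_duct + n_fat)`, the 2.5× mammographic adjustment, and
  BI-RADS-style bins (fatty / scattered / heterogeneous / extremely dense).
- **Tumor embedding** — a 7-mm sphere voxelized by center inclusion, placed
  entirely within ducts at 15–25 mm depth, shallowest admissible site first.
- **Monte Carlo transport** — weighted-packet voxel Monte Carlo at 808 nm
  (Henyey–Greenstein scattering with g = 0.9, continuous absorption
  deposition, Fresnel refraction at refractive-index mismatches, Russian
  roulette, per-packet RNG substreams), scoring per-voxel fluence rate
  φ (mW/cm²) with an exact energy-conservation ledger.
- **Dose** — the UCQR cascade `ETE = ET1 × (f540 × p_multi) × ET3`
  (16.3% × 50%·p × 75%, i.e. 1.2%–6.1% over the canonical p grid) converts
  tumor fluence into a per-session photodynamic dose
  `PD = μa_UCQR · φ · ETE · γ · t / E540` in photons/cm³.
- **Planning** — voxels die when accumulated dose reaches the
  8.6×10¹⁷ photons/cm³ apoptosis threshold; the planner reports per-voxel
  sessions-to-death, cumulative kill fractions and the number of sessions
  to treat the whole tumor.

## Worked example

A synthetic scattered-fibroglandular breast on a 120³ grid, a 7-mm tumor,
one 330 mW/cm² × 606 s session per irradiation:

```r
library(nirpdt)

p   <- synthetic_params(semi_axes_mm = c(16, 16, 35), target_density = 0.16,
                        host_depth_mm = 20, seed = 7)
vol <- generate_phantom(p, dim = c(120, 120, 120), pitch_mm = 0.33)

classify_breast(compute_breast_density(vol))
#> density 0.160 -> adjusted 40.0% -> scattered

emb <- embed_tumor(vol)
emb$tumor
#> tumor_spec: 7 mm sphere, 4945 voxels, depth 15.51 mm, center (45, 32, 99)

fl <- run_transport(assign_optics(emb$volume), beam_spec(), n_photons = 1e6,
                    seed = 1)
fl
#> fluence_volume: 120 x 120 x 120 voxels, 1e+06 packets, seed 1
#>   ledger: absorbed 0.2669, reflected 0.0690, transmitted 0.6642 (sum 1.000000)

mask <- emb$volume$labels == tissue_codes()[["TUMOR"]]
tumor_fluence_summary(fl, mask)$mean
#> 29.9  (mW/cm^2)

for (pm in seq(0.2, 1, 0.2)) {
  plan <- plan_treatment(compute_pd_session(fl, mask, dose_params(p_multi = pm)))
  cat(sprintf("ETE %.1f%%: complete after %d sessions\n",
              round_half_up(100 * compute_ete(dose_params(p_multi = pm)), 1),
              plan$n_complete))
}
#> ETE 1.2%: complete after 27 sessions
#> ETE 2.4%: complete after 14 sessions
#> ETE 3.7%: complete after 9 sessions
#> ETE 4.9%: complete after 7 sessions
#> ETE 6.1%: complete after 6 sessions
```

Reading the output: the generator carved a 16% glandular interior (40%
after the mammographic adjustment — a scattered-fibroglandular breast). The
random duct field happened to admit the sphere slightly shallower than the
20-mm host region, and the shallowest-site criterion took it at 15.5 mm.
The conservation ledger confirms the Monte Carlo run is exact to 10⁻⁶. One
session delivers a mean tumor fluence of ~30 mW/cm², not enough to kill the
deepest tumor voxels in one shot at any cascade efficiency, so the planner
prescribes 6 sessions at the optimistic 6.1% ETE and 27 at the conservative
1.2%. Session counts fall roughly as 1/ETE until the one-session ceiling.

`run_pipeline()` drives all of the above from a YAML/JSON config and writes
a report bundle (classification CSV, tumor spec, fluence + ledger,
depth profile, per-ETE session plans, cross-section maps); a thin CLI lives
at `inst/cli/nirpdt`.

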