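# rapidwashout

Rapid wash-out mapping for contrast-enhanced brain MRI in R.

After gadolinium injection, actively perfused tumor tissue (glioblastoma,
metastases, lymphoma) enhances early — peak enhancement within roughly 3–8
minutes — and then clears the agent, while scar and necrosis accumulate
contrast slowly and are still gaining signal twenty minutes in. Subtracting
a late post-contrast T1-weighted acquisition from an early one therefore
separates **wash-out** (early > late: active tumor cells / vessels, rendered
red) from **wash-in** (late > early: scar / necrosis, rendered green) — the
clinical differential behind pseudoprogression versus true progression —
from two short scans about fifteen minutes apart.

`rapidwashout` implements the full pipeline:

* DICOM series / NIfTI input, grayscale + RGB secondary-capture DICOM and
  NIfTI output (maps align with the source anatomy in a PACS viewer);
* multiplicative bias-field correction (log-domain robust polynomial fit,
  estimated on a 3-fold reduced grid);
* joint mean-intensity normalization of the two series over the brain
  foreground;
* deterministic multi-resolution rigid registration (normalized mutual
  information, 6 DOF) of the late onto the early series;
* subtraction (early − late) and 8-bit encoding with the zero difference
  centred at **127 of 255**, clipped at half the observed value range:
  `g = floor(127.5 (1 + d/C))`, red/green saturating at ±C;
* compartment volumetry with the **wash-out ratio**
  `WO / (WO + WI)`, and rCBV-threshold perfusion volumetry
  (rCBV > 1.2, components under 0.25 cm² in-plane cross-section removed);
* agreement statistics: ICC(2,k) = `(MSR − MSE) / (MSR + (MSC − MSE)/n)`
  with F-based 95% CI, Pearson r / R², Tukey HSD, paired t-tests, Likert
  agreement summaries (0–10 → 0–100%);
* a seeded digital contrast-kinetics phantom (head ellipsoid, tissue
  classes with gamma-variate / saturating-exponential enhancement curves,
  known rigid misalignment, bias fields, Gaussian/Rician noise) with exact
  ground truth, so every stage is testable without patient data.

## Worked example

Generate a misaligned phantom case and run the pipeline:

```r
library(rapidwashout)

truth <- rigid_transform(rotation = c(2, -1, 1.5), translation = c(3, -2, 1))
ph <- generate_phantom(seed = 3, snr = 20, transform = truth)

cfg <- run_config(early = ph$early, late = ph$late, rcbv = ph$rcbv,
                  output_dir = "case_out", seed = 1)
res <- run_case(cfg)
res$volumetry
#> <washout_volumetry> wash-out 3264.0 mm3, wash-in 5448.0 mm3
#>   wash-out ratio 0.375 over 3 lesion component(s)
res$perfusion$volume_mm3
#> [1] 2032
print(res$registration$transform)
#> <washout_rigid> rotation (1.99, -1.284, 1.564) deg, translation (3.015, -2.064, 0.9897) mm
#>   center (0, 0, 0) mm
```

The phantom's enhancing tumor (2 cm³ sphere) plus the vessel drive the
wash-out compartment; the scar sphere drives wash-in. The wash-out ratio
0.375 says wash-out is ~38% of the combined active volume. The recovered
transform sits within a fraction of a voxel of the simulated misalignment
(2°, −1°, 1.5°; 3, −2, 1 mm). `case_out/` holds the difference and gray
maps (NIfTI), gray and RGB DICOM series, compartment masks, a per-lesion
CSV and a JSON manifest recording every setting, the scale factors, the
transform, the clip range, stage timings and a reproducibility checksum.

A shell front end with `compute`, `phantom`, `volumetry` and `stats`
subcommands ships in `inst/cli/rapidwashout`.

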