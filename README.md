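# her2forecast

Imaging-informed forecasting of breast tumor response to neoadjuvant
chemotherapy and HER2-targeted therapy.

## What this package is for

Patients with HER2-positive breast cancer receive months of combination
therapy (docetaxel, carboplatin, trastuzumab, pertuzumab) before surgery,
yet respond very differently, and standard imaging read-outs struggle to
say early who will. `her2forecast` implements a mechanically coupled
reaction–diffusion model of tumor growth and therapy response that is
parameterized voxel-by-voxel from routine multi-modal imaging — diffusion-
weighted MRI (cellularity via the apparent diffusion coefficient),
dynamic contrast-enhanced MRI (chemotherapy delivery via the normalized
enhancement AUC), and radiolabeled-trastuzumab PET (antibody
distribution) — calibrated between a baseline and a mid-therapy scan, and
run forward to the day of surgery to forecast response. It is aimed at
mathematical-oncology researchers who want a complete, tested, end-to-end
reference pipeline: image quantities, tissue mechanics, forward model,
calibration, forecasting, and a virtual-patient generator so every stage
is verifiable without clinical data.

The governing equation for the tumor cell count per voxel $N(\bar x, t)$:

$$\frac{\partial N}{\partial t}
= \nabla\!\cdot\!\big(D\,\nabla N\big)
+ k(\bar x)\,g\big([\mathrm{trastuzumab}]\big)\Big(1-\frac{N}{\theta}\Big)N
- C_{\mathrm{drug}}(\bar x,t)\,N,$$

with stress-damped diffusion $D = D_0 e^{-\gamma \sigma_{vm}}$ (the von
Mises stress $\sigma_{vm}$ comes from a linear-elastic equilibrium forced
by cell gradients), targeted-therapy growth modulation
$g = 1 - 2\mu[\mathrm{trastuzumab}]$, and per-dose exponentially decaying
chemotherapy fields $\alpha_i M(\bar x) e^{-\beta_i (t - t_d)}$. Removing
the $g$ term gives the "MRI-based" model; keeping it gives the
"PET/MRI-based" model. See `vignette("her2forecast-methods")` for the
full account, including an honest analysis of which parameters two
imaging visits can and cannot identify.

## Worked example

Generate the packaged discordant virtual-patient pair and forecast each
patient from the mid-therapy scan to surgery under both model variants:

```r
library(her2forecast)

cfg  <- study_config(mech_cadence = 4, volume_threshold_fraction = 0.05)
pair <- synthetic_patient_pair(seed = 1)

for (nm in names(pair)) {
  study <- generate_longitudinal_study(pair[[nm]], cfg)
  tr <- study$truth
  for (v in c("mri", "pet_mri")) {
    pred <- predict_to_surgery(tr$params, tr$scan1, tr$scan2, tr$drug_maps,
                               tr$domain_model, study$dataset$schedule,
                               variant = v, config = cfg)
    cat(sprintf("%-8s %-8s cellularity change scan2 -> surgery: %6.1f %%\n",
                nm, v, pred$summary$cell_from_scan2))
  }
}
```

Output (seed 1):

```
pcr      mri      cellularity change scan2 -> surgery:  175.8 %
pcr      pet_mri  cellularity change scan2 -> surgery:  -51.2 %
non_pcr  mri      cellularity change scan2 -> surgery:  280.6 %
non_pcr  pet_mri  cellularity change scan2 -> surgery:  229.2 %
```

Without the targeted-therapy term (`mri`) both tumors are predicted to
regrow after the mid-therapy scan; with it (`pet_mri`) the
well-delivered, therapy-sensitive tumor is predicted to keep shrinking
(−51%) while the poorly targeted one regrows — the model separates the
discordant outcomes only when the antibody term is present.

The same separation can be quantified from reported percent-change
summaries alone:

```r
cmp <- compare_models(
  prediction_summary("mri",     -59, 203, -63,  46),
  prediction_summary("pet_mri", -90, -24, -88, -38),
  prediction_summary("mri",     -51,  86, -62,  37),
  prediction_summary("pet_mri", -61,  47, -69,  12))
cmp$pair$separation_increase
#> [1] 41
```

The between-patient difference in scan-2-to-surgery volume change grows
from 9 to 50 percentage points when the targeted term is included — an
increase of 41 points.

Calibration against a two-visit dataset runs through
`derive_patient_quantities()` (ADC, fuzzy-c-means tumor ROI, k-means
tissues, drug maps, cellularity), `calibration_problem()` (factor-4
down-sampling), `calibrate()` (profiled bounded Levenberg–Marquardt), and
`predict_to_surgery()`; `run_patient_analysis()` chains them. NIfTI-1
volumes are read and written with `read_volume()` / `write_volume()`, and
a command-line front end is installed at
`system.file("cli", "her2forecast.R", package = "her2forecast")` with
`synthesize`, `derive`, and `analyze` subcommands.

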