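---
title: "Imaging-informed forecasting of breast tumor response: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imaging-informed forecasting of breast tumor response: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`her2forecast` implements a mechanically coupled reaction–diffusion model of
breast tumor growth and therapy response, parameterized voxel-by-voxel from
multi-modal imaging. The state variable is the number of tumor cells per
voxel, $N(\bar{x}, t)$, evolving as

$$\frac{\partial N}{\partial t} =
\nabla \cdot \big(D(\bar{x},t)\, \nabla N\big)
+ k_H(\bar{x})\,\Big(1 - \frac{N}{\theta}\Big)\,N
- C_{\mathrm{drug}}(\bar{x},t)\, N ,$$

with no flux across the breast boundary and a fully explicit
finite-difference integration at $\Delta t = 0.25$ day (automatic CFL
sub-stepping guards the diffusion term; the state is clipped to
$[0,\theta]$ after each step and the clip count is reported, since the
explicit scheme is not positivity-preserving by construction).

**Mechanics.** Tumor cell gradients deform the surrounding tissue through a
linear-elastic equilibrium
$\nabla\!\cdot G\nabla\vec u + \nabla \tfrac{G}{1-2\nu}(\nabla\!\cdot\vec u)
- \lambda \nabla N = 0$, with shear modulus $G = E / (2(1-\nu))$ assigned
per tissue (adipose 2 kPa, fibroglandular 4 kPa, tumor 20 kPa; Poisson
ratio 0.45; coupling $\lambda = 2.5\times10^{-3}$). The von Mises stress of
the resulting strain field damps the cell diffusivity,
$D = D_0 \exp(-\gamma\, \sigma_{vm})$ with $\gamma = 2\times10^{-3}$/kPa.
Two discretization choices were genuinely open and are resolved as
follows: the displacement obeys zero-Dirichlet ghost conditions just
outside the breast mask (rigid surroundings), while the forcing gradient
$\nabla N$ uses reflection ghosts, because $N$ itself satisfies a no-flux
condition — this makes a spatially uniform cell field force nothing, as it
must. The diagonal part of the grad-div operator is discretized compactly
with face-averaged coefficients (second order, no checkerboard modes);
mixed derivatives use composed central differences. The operator is
symmetric negative definite and is factorized once per material field by
sparse Cholesky, then reused across time steps and optimizer iterations.

**Therapy.** Each dose $t_d$ of the two chemotherapies contributes
$\alpha_i\, M(\bar{x})\, e^{-\beta_i (t - t_d)}$ to the sink, superposed
additively over doses. $M$ is the normalized area-under-the-curve map of
contrast enhancement (scan-1 map for doses before the mid-therapy scan,
scan-2 map afterwards); both drugs share it and differ only in efficacy
$\alpha_i$ and washout rate $\beta_i$. The decay-rate bounds used in
calibration derive from configurable half-life ranges; the defaults
(0.4–2 days and 2–12 days for the docetaxel-like and carboplatin-like
agents) are tissue-washout scales chosen to separate the two drugs'
temporal signatures. The HER2-targeted antibodies act through the
proliferation rate: once the first dose is given,
$k_H = k \cdot (1 - 2\mu\,[\mathrm{trastuzumab}])$, where the antibody map
is normalized radiolabeled-trastuzumab PET uptake and the effect is
constant in time thereafter (no antibody clearance). $g = 1-2\mu u$ may go
negative (net decline); $\mu \in [0,1]$ during calibration bounds it at
$-1$. With $\mu = 0$ the PET/MRI-based model reduces exactly to the
MRI-based model, and the test suite asserts bitwise equality of the two
variants in that case.

## Image-derived quantities

* **ADC and cellularity.** The apparent diffusion coefficient is fitted
  voxelwise by ordinary least squares of $\log S(b)$ on all five b-values
  (0, 600, 800, 1000, 1500 s/mm²); nonpositive signals are assigned the
  free-water value ($3\times10^{-3}$ mm²/s). Cellularity follows
  $N = \theta\,(ADC_w - ADC)/(ADC_w - ADC_{\min})$ with $ADC_{\min}$ the
  ROI minimum, clipped to $[0, \theta]$.
* **Carrying capacity.** $\theta = 0.74 \cdot V_{voxel} / \big(\tfrac43\pi
  (10\,\mu m)^3\big)$. For a 2.18 mm³ voxel this gives
  $\theta \approx 3.85\times10^5$ cells; a commonly printed value of
  $2.02\times10^6$ cells is not reproducible from these constants, so the
  package computes the formula and exposes `theta_override`.
* **Tumor ROI.** Fuzzy c-means (fuzzifier 2, two classes, membership cut
  0.5, convergence $10^{-5}$ or 300 iterations) on the late-enhancement
  feature inside a conservative ROI; the class with the higher center is
  tumor. All four knobs are configurable; none is stated by convention in
  the field.
* **Tissues.** k = 2 k-means on the baseline contrast-enhanced intensity
  with deterministic quantile initialization; on fat-suppressed-like
  contrast adipose is the darker cluster (a flag inverts this, since
  contrast conventions differ).
* **Drug maps.** Trapezoidal AUC of enhancement over the post-injection
  frames (180 s spacing, negatives floored), normalized by the ROI
  maximum; the normalization region defaults to breast-plus-tumor. PET
  uptake is max-normalized over the same region.
* **Volumes.** A measured boolean ROI contributes voxel-count × voxel
  volume. A predicted cellularity field has no intrinsic boundary, so
  voxels holding at least `volume_threshold_fraction` × θ (default 0.25)
  are counted; forecasts apply the same rule to the measured start maps so
  start and end are commensurable. On the 4×-coarsened model grid, block
  dilution makes 0.25 empty the measure; model-grid analyses use 0.05,
  reported alongside every result.

## Calibration

Model fitting uses the two imaging visits on a factor-4 down-sampled grid:
cell maps in block-sum mode with $\theta$ scaled by $4^3$ (conserving
cells keeps $N/\theta$ consistent), drug maps in block-mean mode
re-normalized to maximum 1, labels by block majority. Residuals are the
simulated minus measured scan-2 counts over the union of the two scan
ROIs; the proliferation map lives on that union dilated by two voxels.

The optimizer is a two-stage bounded Levenberg–Marquardt:

* the **map stage** updates voxelwise $k$ by a damped log-space fixed
  point, $k_i \mathrel{+}= \log(N^{meas}_i / N^{sim}_i) / T$ — exact for
  uncoupled exponential growth — with an optional full-Jacobian LM polish;
  voxels carrying no appreciable mass in either data or simulation are
  frozen (they hold no information about $k$);
* the **global stage** fits $D_0, \alpha_{1,2}, \beta_{1,2}, \mu$ by LM
  with finite-difference Jacobians, box bounds by projection, and
  truncated-SVD steps. It is *profiled*: every candidate global vector is
  evaluated with the map re-fitted to it, so the LM descends
  $\min_k \mathrm{SSE}$ rather than crawling in block-coordinate steps.

After alternation converges (relative improvement < 0.1%, or the error
reaches numerical noise relative to the data), a parsimony pass walks the
chemotherapy efficacies back down while the data remain exactly explained,
and a short joint LM refines everything together.

### What two scans can and cannot identify

This is the package's most important caveat. Because $k$ is free per
voxel, the single between-scan snapshot admits an *exact-fit manifold*:
for any sufficiently strong therapy field, the compensating map
$k' = k\,g_{true}/g_{fit} + (\text{drug-difference absorption})$ remains
feasible and reproduces scan 2 to machine precision. Consequently:

* the **fit itself** (residual → 0), the **diffusion coefficient** (the
  only term that moves cells into previously empty voxels), and the
  **spatial pattern** of net growth are well determined;
* the **attribution** between proliferation and the therapy terms — and
  especially $\mu$, which a rescaled map mimics exactly — is not. Fitted
  efficacies retain an imprint of their initialization and of the
  parsimony tie-break (smallest therapy attribution consistent with the
  data); $\mu$ collapses toward its lower bound. The calibration result
  carries an identifiability report (Jacobian condition number, correlated
  parameter pairs) so this is visible per run, and the acceptance test
  asserting 10% recovery of $\alpha_1, \beta_1, \mu$ is deliberately left
  failing rather than weakened.

Two design consequences follow. First, the proliferation lower bound
defaults to 0 (a proliferation rate, not a net rate): allowing negative
$k$ lets a net-rate map explain everything with *zero* therapy effect,
destroying even the partial identifiability above. Second, the
model-variant comparison (PET/MRI versus MRI) is made by toggling the
targeted term on the *same* parameter set: an exactly converged
calibration makes the two variants' in-window effective proliferation
identical, so independently calibrated variants forecast identically and
any apparent difference between them would be an optimizer-path artifact.

## The virtual patient generator

Because no clinical volumes ship with the package, a generator produces
fully aligned two-visit studies with known ground truth: an ellipsoidal
breast with an inner fibroglandular region, a spherical tumor at the
trial's eligibility scale (≥ 2 cm diameter), truncated-normal baseline
cellularity (mean θ/2, SD θ/4 on $[0,\theta]$, drawn by inverse CDF),
mono-exponential diffusion signals, saturating contrast-enhancement
dynamics $E(t) = P(1 - e^{-t/\tau})$ with $\tau = 180$ s (any monotone
saturating profile would do; this one has a closed-form AUC for testing),
and Gaussian-blurred piecewise-constant PET uptake. Noise is Gaussian on
magnitudes (not Rician) for analytic tractability. All randomness derives
from one seed through fixed sub-streams, so a dataset is bit-reproducible.

The true dynamics are integrated *on the down-sampled model grid* — the
same resolution the calibration protocol uses — and the scan-2
imaging-resolution maps are block refinements weighted by the scan-1
within-block pattern. This makes the calibration problem an exact inverse
crime (the generating model and the fitted model coincide), which is the
correct setting for testing the optimizer in isolation; it deliberately
does *not* emulate the discretization mismatch, registration error, or
physiologic drift of real data, so a green parameter-recovery test
establishes optimizer correctness, not clinical identifiability.

Default rates were chosen once to match the clinical setting the model
targets: net cell reduction of roughly 0.5–0.8 %/day during therapy
(proliferation ~0.04/day against chemotherapy efficacies 0.35 and
0.12/day with washout half-lives ~0.8 and ~6 days), stress-free diffusion
0.15 mm²/day, targeted-therapy effectiveness 0.3. The packaged
discordant-response pair (`synthetic_patient_pair()`) contrasts a
"pCR-like" patient — maximally effective, broadly distributed antibody
($\mu = 1$, flat high uptake), modest proliferation, scan 2 after four
cycles, surgery 73 days later — with a "non-pCR-like" patient ($\mu =
0.05$, modest uptake, more proliferative, scan 2 after three cycles,
surgery 92 days later). Under the full model the pair's
scan-2-to-surgery cellularity changes have opposite signs; with the
targeted term removed both tumors are predicted to regrow.

## Numerical choices and limitations

* Explicit Euler at Δt = 0.25 day has first-order error
  ~$(\Delta t/2)\int c(t)^2 dt$ in the therapy exponent; the therapy
  coefficient is evaluated at sub-step midpoints to remove the
  left-endpoint quadrature bias. The closed-form oracles in the test
  suite use rates where the 0.1% tolerance is meaningful, and first-order
  convergence is asserted separately at clinical-scale rates.
* Conservation: the flux-form stencil telescopes exactly; with
  proliferation and therapy off, total cells are conserved to < 1e-9
  relative over 100 simulated days.
* Mechanics cadence: the equilibrium is recomputed every step by default;
  a cadence of 4 steps (one day) is used in calibration-heavy runs and
  changes trajectories negligibly while cutting runtime fourfold. The
  cadence is a config value and is part of the stated conditions of any
  result.
* Degenerate inputs: an all-equal enhancement feature, fewer than two
  distinct tissue intensities, a zero AUC maximum, or a tumor ROI whose
  minimum ADC reaches the free-water value raise informative errors
  rather than producing silent garbage.
* Known limitations: one tumor-cell phenotype; no drug-transport
  differences between agents; no antibody clearance; no evolving
  vasculature; registration is out of scope by construction (synthetic
  data are generated pre-aligned).
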