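---
title: "Mueller-matrix polarimetry of fibrous tissue: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mueller-matrix polarimetry of fibrous tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarmm)
```

# The measurement model

A transmission Mueller polarimeter illuminates the sample with at least four
independent polarization states (Stokes vectors, columns of `[S_in]`) and
analyzes the transmitted states `[S_out]`. The per-pixel Mueller matrix is
the solution of the linear measurement equation

$$ [S_\mathrm{out}] = M\,[S_\mathrm{in}], \qquad
   M = [S_\mathrm{out}]\,[S_\mathrm{in}]^{+}, $$

an exact inverse for the minimal four-state set and a least-squares solution
for more states (`reconstruct_mm()`). The package convention throughout is
the Stokes basis (I, Q, U, V) with horizontal linear polarization mapped to
+Q. The default generator (`default_psg()`) models a fixed 0° polarizer
followed by a quarter-wave plate at −45°, 0°, 30° and 60°; the hardware this
emulates fixes the optical layout but not the rotation angles, so the angles
were chosen once to keep the 4×4 state matrix well conditioned (condition
number ≈ 3.6) and are configurable. `stokes_set()` refuses generator sets
within 10 orders of magnitude of rank deficiency and reports the condition
number in the error.

Simulated acquisition (`simulate_measurement()`) projects each output Stokes
vector onto an ideal six-state analyzer, adds Gaussian noise to the analyzer
*intensities* with relative scale `noise_sigma`, optionally averages
repeated frames, and reassembles Stokes vectors by least squares. Additive
Gaussian noise is a deliberate simplification of shot noise: it keeps the
noise-scaling law linear (reconstruction RMSE ∝ σ, ∝ 1/√frames), which is
what the round-trip tests verify; a Poisson model would change constants
but not the pipeline.

# Polarization basic parameters

## Polar decomposition

`mmpd()` factorizes each normalized pixel as \(M = M_\Delta M_R M_D\):
the diattenuator \(M_D\) is built from the first row, the remainder
\(M' = M M_D^{-1}\) is split into depolarizer and retarder through the eigen
solution of \(m' m'^T\) with the determinant-sign rule. Scalar parameters
follow the conventional closed forms (see the README for the formulas);
the fast-axis orientation and optical rotation are computed with
quadrant-aware two-argument arctangents, retardance on the branch
\([0, \pi]\), axial angles reported in degrees on \([0°, 180°)\).

Numerical choices worth noting:

- **Depolarization** uses the 3×3 depolarizer submatrix trace,
  \(\Delta = 1 - |\mathrm{tr}\, m_\Delta|/3\), which keeps \(\Delta \in [0,1]\);
  reading the trace over the full 4×4 factor would require an extra −1 and
  is equivalent for diagonal depolarizers.
- **Degeneracy**: pixels whose retained 3×3 submatrix has
  \(|\det| \le 10^{-12}\) (fully depolarizing) or whose diattenuation
  saturates are flagged `degenerate` and yield `NA` parameters rather than
  an error; downstream statistics skip them.
- **Orientation is conditional on retardance**: where \(\sin\delta \to 0\)
  the fast axis is physically meaningless and its value is numerical noise;
  tests and users should condition orientation statistics on
  \(\sin\delta\) bounded away from zero.
- The implementation is vectorized over pixels with closed-form symmetric
  3×3 eigenvalues and adjugate inverses; the test suite checks it against an
  independent per-pixel implementation using `eigen()`/`solve()`.

## Transformation (MMT) parameters

`mmt()` computes the closed-form element combinations (`D_L`, `P_L`, `q_L`,
`r_L`, `t1`, `b`, `A`, `|B|`, `‖B‖`, `m14`, `m41`, `CD`, `m44`, `α_r`).
Two typographic ambiguities in the source literature were resolved as
follows:

- `t1` defaults to the rotation-invariant form
  \(\tfrac12\sqrt{(m_{22}-m_{33})^2 + (m_{23}+m_{32})^2}\). The typeset
  variant \(\tfrac12\sqrt{(m_{22}-m_{33})^2 + (m_{22}+m_{33})^2}\) equals 1
  on the identity and is *not* rotation invariant, contradicting its own
  classification; it remains available behind `t1_printed = TRUE`.
- The quantity `b` entering \(A = 2bt_1/(b^2+t_1^2)\) is never defined where
  `A` is introduced; it is taken as \(b = \tfrac12(m_{22}+m_{33})\), the
  standard MMT definition. `A` is defined as 0 when \(b = t_1 = 0\).

Exactly 15 parameters are rotation invariant —
\(\{D, \Delta, \delta\}\) plus the 12 non-angular MMT quantities — and
`pbp_stack()` carries a per-parameter flag. The two axial angles
\(\theta, \alpha_r\) shift by exactly the sample rotation modulo 180°, which
the acceptance suite verifies at 10°, 30° and 77°. The identity of the
15-parameter feature set is itself an inference (the count matches and the
optical-rotation angle \(\alpha\) is excluded along with the axial angles);
`pbp_features()` accepts any rotation-invariant subset.

# Statistics

Group comparison uses proportion-normalized frequency distribution
histograms (`compute_fdh()`, default 100 bins over a parameter's natural
range so curves overlay across groups) and first-order statistics with the
rotation-variance rule (`summary_stat()`): means for rotation-invariant
parameters, axial circular standard deviations for orientation angles. The
axial SD doubles the angle, takes the resultant length
\(R = |\langle e^{2i\theta}\rangle|\) and reports
\(\tfrac12\sqrt{-2\ln R}\) in degrees — exact for wrapped-normal axial data
and immune to the 0°/180° seam. The source text contains an apparent word
swap ("standard deviation of rotation-invariant parameters"); the
implementation follows the consistent reading used everywhere else in the
same work: mean ↔ invariant, SD ↔ variant.

Per-parameter recovery is the ratio `S_parameter = p / p_n` against the
normal-group statistic. Statistics are computed per region of interest and
averaged (the sampling design of the original study); a pooled-pixel mode
exists behind a flag.

# The learned feature (PFP)

`fit_pfp()` maximizes \(F(W) = (\tilde\mu_1-\tilde\mu_2)^2/(D_1+D_2)\) over
weight vectors. Because the between-class scatter
\(S_u = (\mu_1-\mu_2)(\mu_1-\mu_2)^T\) is rank one, the maximizer is the top
eigenvector of \(S_p^{+} S_u\), computed here through singular-value
machinery with a relative cutoff of \(10^{-10}\); the closed form
\(S_p^{+}(\mu_1-\mu_2)\) serves as the independent oracle in tests.
Resolved ambiguities, each switchable:

- **Standardization** (default on): raw PBPs mix radians with unit-interval
  quantities, so features are z-scored with center/scale pooled over both
  classes; weighting coefficients are then comparable across parameters.
  Raw mode: `standardize = FALSE`.
- **Scatter normalization** (default `"normalized"`): the defining equation
  normalizes projected variances by \(1/N_j\) while the scatter-matrix form
  uses raw sums; with unbalanced classes these differ. The default sums the
  class covariances (consistent with the definition of \(F\));
  `scatter = "unnormalized"` reproduces the raw-sum form.
- The denominators typeset as \(W^T S W^T\) are read as quadratic forms
  \(W^T S W\), and \(S_d \equiv S_p\).
- **Sign**: \(W\) is fixed so the normal class projects higher
  (\(\tilde\mu_1 > \tilde\mu_2\)); healthy tissue has high PFP.

Degenerate inputs fail loudly: coincident class means ("no class
separation"), numerically zero within-class scatter, fewer pixels than
features.

The treatment score
\(S = 50\,\big(\frac{|\tilde u_r-\tilde\mu_2| - |\tilde u_r-\tilde\mu_1|}
{|\tilde u_r-\tilde\mu_2| + |\tilde u_r-\tilde\mu_1|} + D_1/D_r\big)\)
is invariant under any consistent affine rescaling of the projection and
satisfies the forced identities \(S = 100\) at the normal statistics,
\(S = 0\) at the model center with normal width, and \(S = 50 D_1/D_r\) at
the midpoint. Note \(S\) is unbounded below for very wide distributions and
exceeds 100 for groups *narrower* than normal; it is a ranking device, not
a probability.

# The phantom world

`generate_phantom()` replaces unavailable tissue scans. Each group is an
effective-optics description (`group_preset`): per-pixel
depolarizer·retarder·diattenuator composition with spatially smoothed
Gaussian random fields for retardance, diattenuation and axial orientation
(wrapped to \([0°,180°)\)), air lacunae carved by thresholding a smooth
field at the fill fraction, a transmittance field, and measurement noise
added in the simulated acquisition. Smoothed fields are rescaled back to
their target marginal SD, so preset SDs are exact population parameters.
The retardance–birefringence link \(\delta = 2\pi\,\Delta n\, t/\lambda\)
is maintained inside every preset (the literature's two inconsistent
birefringence figures, 0.0013 and 0.013, are exposed as
`reference_birefringence()` and asserted nowhere).

The default presets are the stated world and were fixed before any test was
run: normal (δ = 1.0 rad, D = 0.05, σθ = 5°, high polarization purity),
model (δ = 0.4, D = 0.15, σθ = 35°, stronger depolarization, 20% air),
and treatment groups graded so that medium sits nearest normal — and at
δ = 1.2 rad deliberately *beyond* it, encoding the observed
better-than-normal retardance recovery — followed by high, with low and
positive remaining near the model group. ROI counts follow the original
sampling design (16 normal, 22 model, 10/12/13/15 treatments). Measurement
noise defaults to 1% relative intensity — a typical camera noise floor, and
a structural necessity: a noise-free phantom makes all 15 features exact
functions of three underlying fields, collapsing the within-class scatter
to (numerical) rank three and making Fisher separation meaningless.

**What a green test establishes — and what it does not.** The phantom
validates the *machinery*: decomposition correctness, rotation behavior,
estimator consistency, the Fisher optimality, and that the pipeline
recovers orderings that are designed into the presets. It does not validate
the biology: the printed tissue-study values (e.g. its F table or weighting
coefficients) come from scans that are not public and are not asserted.
Scattering-specific behavior — notably diattenuation trends with fiber
diameter, which in the original work come from a photon-transport Monte
Carlo over sphere/cylinder scatterers — is outside this forward model and
documented as such.

# Reproducibility and the pipeline

`run_pipeline(study_config(seed = ...))` executes phantom → measurement →
reconstruction → normalization → PBPs → ROI statistics/S_parameter → PFP
fit → projection → scores/FDH report → staining, and writes a manifest.
All randomness derives from the root seed through substreams keyed by
*preset content*, not group name: renaming a group cannot change results,
two identically configured groups produce identical realizations (which the
PFP fit then rejects as zero separation), and manifests are bit-identical
across reruns (timings are logged outside the manifest).

Virtual staining maps background and the lowest PFP band to blue, the mid
band to green and the high band to orange-red with continuous within-band
shading. Default breaks are percentile-based with the green/orange boundary
at the median projected model-class value when a model is supplied; any
absolute breaks can be given. Band fractions are invariant under strictly
increasing transforms of the PFP when breaks are percentiles.

# Known limitations

- No physical-realizability (Cloude) filtering; heavily noise-corrupted
  matrices propagate into flagged or biased parameters instead of being
  projected back to the physical cone.
- The analyzer model is ideal and noise is additive Gaussian; calibration
  error and shot noise are out of scope.
- Retardance fields are clipped at 0 and π, slightly biasing extreme preset
  settings; orientation is undefined at clipped-to-zero retardance pixels.
- File containers are plain text (TSV/JSON/PPM) for portability; they are
  not space-efficient for large images.
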