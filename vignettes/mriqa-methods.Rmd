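---
title: "Scanner QA metrics for multimodal MRI: models and design"
author: "mriqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanner QA metrics for multimodal MRI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mriqa)
```

# The problem

Longitudinal and multi-site neuroimaging studies must distinguish
biological change from scanner drift: hardware repairs (for instance a
gradient-coil replacement), software upgrades, or simply moving a
participant from one nominally identical scanner to another can shift
derived measurements. `mriqa` implements a compact battery of
quantitative metrics over the three standard acquisitions — T1
structural, resting-state BOLD, and diffusion-weighted imaging — plus
the reliability statistics used to compare scanner conditions, so that
a site can run the same battery on every session (human volunteer or
phantom) and detect hardware-induced shifts.

Every metric is testable without scanner data: the package ships
synthetic phantom generators with exact ground truth, and the test
suite exercises each metric against independent oracles on those
phantoms.

# Metrics

## Structural: ROI volumes and global intensity normalization

Session-to-session global intensity varies with coil loading and
receiver gain, so each T1 volume is first multiplied by a scaling
factor $G_i = m_{\mathrm{ref}} / S_i$, where $S_i$ is the mean
intensity inside the whole-brain mask and $m_{\mathrm{ref}}$ a fixed
reference mean. The reference defaults to 1000 (arbitrary units); its
exact value is immaterial because every downstream metric is either
intensity-invariant (volumes, stretch, the QC ratio — a ratio of
means) or computed on normalized data consistently across sessions.

ROI volume is voxel counting: $V = n \cdot v_x v_y v_z / 1000$ cm³.
Segmentation itself is out of scope — label maps are inputs — so the
metric isolates acquisition geometry from segmentation engineering.

## Structural: stretch factor

Each session's T1 is registered to a template with a 12-parameter
affine (3 translations, 3 rotations, 3 scales, 3 skews). The linear
part $L$ is factored

$$L = R\,S\,K, \qquad S = \mathrm{diag}(s_x, s_y, s_z),$$

with $R$ a rotation and $K$ unit upper-triangular (the Gram–Schmidt/QR
factorization, as in FSL's `avscale`). The per-axis stretch factors
$s_x, s_y, s_z$ index geometric distortion along each gradient axis; a
value of 1 means no rescaling is needed to reach the template. The
determinant $\det L = s_x s_y s_z$ — the volumetric analogue of an
atlas scaling factor — is reported alongside, and the identity
$\prod_i s_i = \det L$ is enforced as a class invariant. Two template
modes are supported: an external standard-space template, or one
designated session's own T1 as a subject-specific template.

Registration minimizes the mean squared difference of z-scored
intensities over a multi-resolution pyramid (subsampling 4, 2, 1),
with a deterministic coordinate-wise line search followed by a
Nelder–Mead polish at each level. Design choices worth recording:

* **Cost.** Normalized MSE rather than correlation ratio: QA
  comparisons are within-modality, where MSE after mean/variance
  normalization is adequate, simpler, and exactly minimized (cost 0)
  at perfect alignment — which makes self-registration exact rather
  than approximate.
* **Centering.** Rotation/scale/skew are applied about the template
  center, not the world origin. This decouples them from the
  translation parameters (a scale about a corner displaces the head
  and must be undone by translation, which cripples coordinate
  descent). The linear part, hence the stretch decomposition, is
  unaffected by the choice of center.
* **Failure mode.** If the optimized cost does not improve on the
  identity beyond a tolerance, the identity is returned with
  `converged = FALSE` rather than a spurious transform.
* **Reflections.** A negative determinant is refused with an error
  naming the flipped axis; stretch factors are positive by definition.

## Structural QC: background intensity ratio

Motion during the T1 scan produces ghosting along the anterior–
posterior phase-encoding direction, which raises the background
intensity anterior to the head. The screening metric is the ratio of
mean background intensity in a region anterior to the head over a
region superior to the eyes (a reference equally far from the brain
but off the phase-encoding axis). A ratio above 1 flags the scan for
visual inspection. The default region bounds are closed 1-based voxel
intervals [90, 109] × [246, 255] × [186, 225] (anterior) and
[65, 84] × [156, 195] × [246, 255] (superior) on a 256-matrix
acquisition; the closed-interval reading is the one that makes each
region exactly 20 × 10 × 40 = 20 × 40 × 10 = 8000 voxels, and the
bounds are configurable for other matrices.

```{r qc}
qcRegionVoxelCounts(qcRoiBounds())
```

## BOLD: temporal signal-to-noise ratio

tSNR is computed on the **ROI-mean time course**: all ROI voxels are
averaged within each volume to give $m(t)$, and

$$\mathrm{tSNR} = \bar m / \mathrm{sd}(m),$$

with the sample standard deviation ($n-1$). Aggregating before the
ratio reflects that voxels of one functional network share coherent
spontaneous fluctuations, and it is the only reading under which
network-level tSNR values in the many hundreds are attainable — the
per-voxel ratio at typical noise levels is an order of magnitude
lower. A voxelwise mode (median of per-voxel tSNR) is available behind
a flag.

The preprocessing chain before tSNR is: discard the first 4 volumes;
spatially smooth with a Gaussian kernel of 5 mm FWHM (per-axis
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ in mm, scaled by the voxel
dimensions, kernel row-renormalized at the lattice edges so constant
images are preserved); high-pass filter with a 150 s cutoff; regress
out nuisance series (the six motion parameters and any configured
mask-mean signals), reinstating each voxel's temporal mean so the
ratio stays defined. All cutoffs and the kernel width are arguments
with these defaults.

Two deliberate deviations from common engine internals:

* **High-pass filter.** The drift basis consists of whole-cycle sine
  *and* cosine harmonics with periods at or above the cutoff,
  projected out by least squares. Unlike a cosine-only basis, this
  removes a slow drift of *any phase* at the retained frequencies
  completely, and full-cycle harmonics sum to zero so the temporal
  mean is preserved exactly. It differs from a Gaussian-weighted
  running-line filter mainly in its sharp frequency cutoff.
* **Motion displacement.** The QC summary reports the maximum
  Euclidean translation difference between adjacent volumes in mm;
  rotations are reported separately as a maximum adjacent angle rather
  than folded into millimetres, because any mm-equivalent requires an
  arbitrary head-radius convention.

Slice-time correction and motion correction are intentionally not
implemented: the toolkit consumes realigned data plus the exported
motion parameter files, which isolates the QA metrics from
realignment engineering (phantoms are motion-free).

## Diffusion: FA and MD

Per voxel, the single-tensor model $S = S_0 e^{-b\,g^\top D g}$ is
log-linearized and fit by ordinary least squares with the design row

$$(-b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z,
   -2b g_y g_z, 1)$$

mapping $(D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz}, \ln S_0)$
to $\ln S$. From the eigenvalues $\lambda_1 \ge \lambda_2 \ge
\lambda_3$:

$$\mathrm{MD} = (\lambda_1 + \lambda_2 + \lambda_3)/3, \qquad
\mathrm{FA} = \sqrt{\tfrac{3}{2}}\,
\frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}
     {\sqrt{\sum_i \lambda_i^2}}.$$

Numerical policy: OLS on log-signals (deterministic, the classic FDT
default; weighted or nonlinear fits are out of scope); signals clamped
at $10^{-6} \times \hat S_0$ before the log; negative eigenvalues
clamped to zero with a per-voxel flag; all-zero voxels flagged
degenerate and excluded from ROI summaries. On noiseless phantoms the
fit is exact to floating-point precision, which the tests assert at
1e-9.

```{r fa}
fa(1.7e-3, 0.3e-3, 0.2e-3)   # prolate, WM-like
md(1.7e-3, 0.3e-3, 0.2e-3)   # mm^2/s
```

# Reliability statistics

Group differences across $k$ scanner conditions use one-way ANOVA
(`oneWayAnova`, $F_{k-1,\,N-k}$). `anovaFromSummary` reconstructs the
balanced one-way ANOVA from per-group means and standard errors
(per-group sd $= \mathrm{se}\sqrt n$), which is exact for balanced
designs and lets printed summary tables be re-analyzed.

Test–retest reliability uses the intraclass correlation

$$\mathrm{ICC} = \frac{\mathrm{BMS} - \mathrm{EMS}}
  {\mathrm{BMS} + (k-1)\,\mathrm{EMS}},$$

with BMS the between-subject mean square and EMS the residual mean
square after removing subject *and* condition effects — the
Shrout–Fleiss consistency form ICC(3,1). Near 1, between-subject
differences dominate the condition error (good hardware stability);
near 0, condition error dominates. Two policy choices: the agreement
form ICC(2,1), which charges condition shifts to the error, would
give different values — the consistency form is the documented default
because the quoted 0-to-1 range only holds for it after clipping; and
negative raw values are retained alongside the clipped headline value.
An all-equal table has no variance to attribute and is flagged
undefined rather than reported as any number.

```{r icc}
m <- matrix(rnorm(6, sd = 2), 6, 3) + matrix(rnorm(18, sd = .5), 6, 3)
iccConsistency(m)
```

Post-hoc comparisons are paired t-tests of each condition against a
designated reference condition, uncorrected (the battery reports raw
p-values; multiplicity policy is left to the study).

# The phantom generators

`makeStructuralPhantom` rasterizes ellipsoids (voxel-center inequality
$\sum ((x-c)/a)^2 \le 1$) or half-open boxes onto the lattice, giving
label maps whose voxel counts — hence volumes — are exact by
construction; overlapping regions are refused so ground truth is
unambiguous. Background air carries Rayleigh noise (magnitude of two
Gaussian quadrature channels), and an optional anterior ghost adds a
constant to one channel inside a configurable region, emulating
phase-encode ghosting for the QC ratio.

`makeBoldPhantom` programs the ROI-mean time course directly:
baseline + sinusoidal drift + nuisance contributions + shared Gaussian
fluctuation, with independent voxel noise on top. The shared
fluctuation mirrors network-coherent resting-state signal and sets the
programmed tSNR $= \mathrm{baseline}/\mathrm{sd}_{\mathrm{shared}}$;
voxel noise averages down by the ROI size and perturbs the ROI mean
only at second order (the exact inflation,
$\sqrt{1 + \mathrm{sd}_v^2 / (n\,\mathrm{sd}_s^2)}$, is what the
recovery tests assert against). The nuisance series are smooth
standardized random walks, returned alongside the image so the
regression step can be exercised with known truth.

`makeDwiPhantom` evaluates the tensor signal model in closed form per
region; Rician noise, when enabled, is the magnitude of
$(S + n_1, n_2)$ with $n \sim N(0, \sigma)$ — the correct
magnitude-image noise model, not its Gaussian approximation.

What the phantoms do *not* emulate: anatomy, partial-volume tissue
mixtures, k-space artifacts, susceptibility distortion, physiological
noise spectra, or actual head motion. Passing tests therefore
demonstrate that the *metrics and statistics* are computed correctly
and recover programmed truth — not that any particular scanner meets a
quality bar on real data.

# Numerical notes and problem sizes

* All randomness flows through explicit seeds; phantoms are
  bit-identical across runs for a fixed seed, and the generators
  restore the caller's RNG state.
* Trilinear interpolation with zero fill outside the field of view is
  used for all resampling; Gaussian smoothing truncates the kernel at
  6σ (normalization error below 1e-9).
* One expected small bias is documented rather than hidden: ordinary
  least squares residuals understate the noise sd by
  $\sqrt{(T-1-p)/(T-1)}$ after projecting out $p$ regressors, so
  pipeline tSNR runs ~2 % high at $T = 240$ with the default drift
  basis and a couple of nuisance regressors. The sampling-distribution
  tests account for it; users comparing pipelines with different
  regressor counts should too.
* The test suite and the demo study run on deliberately small
  problems — lattices of 20–40 voxels per axis, series of 64–244
  volumes, 6 × 3 study layouts — chosen so the full battery exercises
  every code path in well under a minute per component while the
  phantom signal-to-noise keeps every assertion far from its
  tolerance.
* In the demo study the per-subject tSNR baselines are drawn from
  roughly 350–1050 with unit shared noise, matching the magnitude and
  the wide between-subject spread of network tSNR reported for 3 T
  human data; volumes and tensor eigenvalues likewise vary between
  subjects but not between conditions, so ANOVA should be null and
  ICC high — which is exactly what the study-level tests assert.

# Limitations

Segmentation, skull stripping beyond a threshold mask, nonlinear
registration, eddy-current/motion correction, tractography and
multi-shell diffusion models are out of scope; where such steps are
needed they are inputs. The registration optimizer is local: it is
intended for the small transforms that arise in scanner QA
(self-registration, session-to-session drift, programmed phantom
transforms), not for arbitrary initial misalignments.
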