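# mriqa — reproducibility and QA metrics for multimodal MRI

`mriqa` is an R toolkit for scanner quality assurance and test–retest
reliability in brain MRI. It targets the question every longitudinal or
multi-scanner study has to answer: *did the hardware (a gradient-coil
replacement, a second "identical" scanner, a software upgrade) shift my
measurements?* It computes a compact battery of metrics over the three
standard acquisitions and the statistics needed to compare scanner
conditions:

* **T1 structural** — global intensity normalization (`G = m_ref / S`),
  ROI volumetry from label maps (cm³), the per-axis **stretch factor**
  from 12-parameter affine registration (linear part factored
  `L = R·S·K` with `S = diag(sx, sy, sz)`; `det L = sx·sy·sz` reported
  as the volumetric analogue), and a background-intensity motion
  screen (anterior/superior ratio > 1 flags ghosting).
* **Resting-state BOLD** — temporal SNR of the ROI-mean time course,
  `tSNR = mean(m) / sd(m)`, after the standard chain: discard 4
  volumes, 5 mm FWHM Gaussian smoothing, 150 s high-pass, nuisance
  regression (motion + mask means); plus the maximum adjacent-volume
  displacement from motion parameter files.
* **Diffusion** — per-voxel tensor fit by OLS on log-signals
  (`ln S = ln S0 − b gᵀDg`), eigenvalue maps, and ROI summaries of
  `MD = (λ1+λ2+λ3)/3` and
  `FA = √(3/2)·√Σ(λi−λ̄)² / √Σλi²`.
* **Reliability** — one-way ANOVA across conditions (including exact
  reconstruction from printed mean ± SE tables), Shrout–Fleiss
  consistency ICC(3,1) `= (BMS − EMS) / (BMS + (k−1)·EMS)`, and paired
  post-hoc t-tests against a reference condition.

Everything is testable without scanner data: the package generates
structural, BOLD and DWI phantoms with exact ground truth (known
region volumes, programmed tSNR, known diffusion tensors) and the test
suite verifies each metric against independent oracles on them.

File formats are the field's text/NIfTI staples: NIfTI-1 images, FSL
bval/bvec tables, FSL `.mat` 4×4 affines, 6-column `.par` motion files,
YAML study configs.

## Worked example

Generate a full 6-subject × 3-condition synthetic study (structural +
BOLD + DWI per session), run every metric, and get the reliability
report:

```r
library(mriqa)
res <- demoPhantomStudy(seed = 1, outdir = "demo", size = "small")
head(res$report$summary, 3)
#>             metric condition     mean        se n
#> 1  volume.thalamus         1 3.797333 0.4976732 6
#> 2  volume.thalamus         2 3.797333 0.4976732 6
#> 3  volume.thalamus         3 3.797333 0.4976732 6

for (met in names(res$report$icc)) {
  an <- res$report$anova[[met]]
  cat(sprintf("%-18s F=%5.2f p=%4.2f ICC=%4.2f\n",
              met, an@F, an@p, res$report$icc[[met]]@icc))
}
#> volume.thalamus    F= 0.00 p=1.00 ICC=1.00
#> stretch.x          F=32.31 p=0.00 ICC=0.31
#> stretch.y          F=16.84 p=0.00 ICC=0.42
#> stretch.z          F=17.05 p=0.00 ICC=0.41
#> tsnr.dmn           F= 0.02 p=0.98 ICC=0.94
#> fa.wm              F= 0.00 p=1.00 ICC=1.00
#> md.wm              F= 0.00 p=1.00 ICC=1.00
```

Reading this: volumes, tSNR, FA and MD vary between the synthetic
subjects but not between conditions, so ANOVA is null (`p ≈ 1`) and
ICC is high — the signature of stable hardware. The stretch factors
use each subject's condition-2 image as the registration template, so
condition 2 is exact (1.0000 by construction) while conditions 1 and 3
carry a tiny noise-driven bias (~5 × 10⁻⁴); with zero programmed
between-subject variance in geometry, even that minuscule condition
effect makes ANOVA significant and drops ICC — exactly the known
sensitivity of subject-specific-template stretch factors to
session-specific structure.

Individual metrics are plain function calls:

```r
ph <- makeStructuralPhantom(structuralPhantomSpec(), seed = 1)
roiVolumes(ph$labels)
#> thalamus-like  putamen-like
#>         4.029         0.491

fa(1.7e-3, 0.3e-3, 0.2e-3)   # 0.8358681
md(1.7e-3, 0.3e-3, 0.2e-3)   # 0.0007333333 mm^2/s

anovaFromSummary(means = c(0.44, 0.44, 0.44),
                 ses = c(0.03, 0.04, 0.05), nPerGroup = 6)
#> ANOVA (from-summary): F(2, 15) = 0.000, p = 1
```

A thin command-line dispatcher over the same functions is included at
`inst/scripts/mriqa.R` (subcommands `t1-volumes`, `t1-stretch`,
`t1-qc-ratio`, `bold-tsnr`, `dti-fit`, `dti-roi`, `report`, `demo`).

See `vignettes/mriqa-methods.Rmd` for the models, parameter defaults,
numerical policies, and what the phantom tests do and do not
demonstrate.

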