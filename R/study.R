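# Study orchestration: run every configured metric over a set of
# sessions (subject x condition), assemble the MetricTable, and emit the
# reliability report plus per-session QC. demoPhantomStudy() builds a
# complete synthetic study exercising the whole toolkit.

#' Read a study configuration
#'
#' Loads a YAML study description: an `options` block (referenceCondition,
#' referenceMean, fwhm, highpass, discard, computeStretch, qcBounds) and
#' a `sessions` list, each session giving `subject`, `condition` and the
#' per-modality file paths (`t1`, `t1Labels`, `bold`, `boldRoi`,
#' `motion`, `nuisance`, `dwi`, `bval`, `bvec`, `dwiLabels`).
#'
#' @param path path to the YAML file.
#' @return The configuration list.
#' @export
readStudyConfig <- function(path) {
  .stopIf(!file.exists(path), "config not found: %s", path)
  cfg <- yaml::read_yaml(path)
  .stopIf(is.null(cfg$sessions), "config has no sessions")
  cfg
}

.studyDefaults <- function(opts) {
  defs <- list(referenceCondition = NULL, referenceMean = 1000,
               fwhm = 5, highpass = 150, discard = 4L,
               computeStretch = TRUE, qcBounds = NULL,
               registration = list())
  for (nm in names(opts)) defs[[nm]] <- opts[[nm]]
  defs
}

.sessionMetrics <- function(sess, opts, stretchTemplate) {
  rows <- list()
  qc <- list(subject = sess$subject, condition = sess$condition,
             t1Ratio = NA_real_, maxTranslation = NA_real_,
             maxRotation = NA_real_, error = NA_character_)
  addRow <- function(metric, value)
    rows[[length(rows) + 1L]] <<- data.frame(
      subject = sess$subject, condition = sess$condition,
      metric = metric, value = value)
  nameVec <- function(x) if (is.null(x)) NULL else unlist(x)
  if (!is.null(sess$t1)) {
    t1 <- readNiftiImage(sess$t1)
    if (!is.null(sess$t1Labels)) {
      labs <- readLabelMap(sess$t1Labels,
                           regionNames = nameVec(sess$t1RegionNames))
      norm <- globalIntensityNormalize(t1, labelArray(labs) != 0L,
                                       opts$referenceMean)
      t1 <- norm$image
      vols <- roiVolumes(labs)
      for (nm in names(vols)) addRow(paste0("volume.", nm), vols[[nm]])
    }
    if (!is.null(opts$qcBounds)) {
      b <- opts$qcBounds
      bounds <- qcRoiBounds(
        anterior = matrix(unlist(b$anterior), 3L, 2L, byrow = TRUE),
        superior = matrix(unlist(b$superior), 3L, 2L, byrow = TRUE))
      qr <- backgroundMotionRatio(t1, bounds)
      qc$t1Ratio <- qr$ratio
      addRow("qcRatio", qr$ratio)
    }
    if (isTRUE(opts$computeStretch) && !is.null(stretchTemplate)) {
      regOpts <- do.call(registrationOptions, opts$registration)
      xf <- registerAffine(t1, stretchTemplate, regOpts)
      dec <- decomposeScales(xf)
      addRow("stretch.x", dec@scales[1])
      addRow("stretch.y", dec@scales[2])
      addRow("stretch.z", dec@scales[3])
    }
  }
  if (!is.null(sess$bold)) {
    bold <- readNiftiImage(sess$bold)
    roi <- readLabelMap(sess$boldRoi,
                        regionNames = nameVec(sess$boldRegionNames))
    reg <- NULL
    if (!is.null(sess$motion)) {
      tr <- readMotionParams(sess$motion)
      disp <- maxAdjacentDisplacement(tr)
      qc$maxTranslation <- disp$maxTranslation
      qc$maxRotation <- disp$maxRotation
      mp <- motionParams(tr)
      mp <- mp[, apply(mp, 2L, stats::sd) > 0, drop = FALSE]
      if (ncol(mp) > 0L) reg <- mp
    }
    if (!is.null(sess$nuisance))
      reg <- cbind(reg, as.matrix(utils::read.table(sess$nuisance)))
    if (!is.null(reg))
      reg <- reg[(opts$discard + 1L):nrow(reg), , drop = FALSE]
    pre <- preprocessBold(bold, discard = opts$discard, fwhm = opts$fwhm,
                          highpass = opts$highpass, regressors = reg)
    labs <- labelArray(roi)
    for (l in sort(setdiff(unique(as.vector(labs)), 0L))) {
      res <- roiTsnr(pre, labs == l)
      addRow(paste0("tsnr.", regionNames(roi)[[as.character(l)]]),
             res@tsnr)
    }
  }
  if (!is.null(sess$dwi)) {
    dwi <- readNiftiImage(sess$dwi)
    scheme <- readBvalsBvecs(sess$bval, sess$bvec)
    labs <- readLabelMap(sess$dwiLabels,
                         regionNames = nameVec(sess$dwiRegionNames))
    tf <- fitTensor(dwi, scheme, labelArray(labs) != 0L)
    famap <- faMap(tf); mdmap <- mdMap(tf)
    for (l in sort(setdiff(unique(as.vector(labelArray(labs))), 0L))) {
      nm <- regionNames(labs)[[as.character(l)]]
      addRow(paste0("fa.", nm),
             roiMeanMetric(famap, labelArray(labs) == l)$mean)
      addRow(paste0("md.", nm),
             roiMeanMetric(mdmap, labelArray(labs) == l)$mean)
    }
  }
  list(rows = rows, qc = qc)
}

#' Run a full reproducibility study
#'
#' Computes every configured metric for every session, assembles the
#' subject x condition x metric [MetricTable], and produces the
#' reliability report ([metricReport()]) plus a per-session QC block
#' (T1 background ratio, maximum adjacent motion). A failing session is
#' logged, marked, and skipped; ICC is skipped (with a warning) for
#' metrics with incomplete crossings.
#'
#' @param config a configuration list (see [readStudyConfig()]) or the
#'   path to a YAML config.
#' @return A list with `table` ([MetricTable]), `report`
#'   (see [metricReport()]) and `qc` (data.frame).
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- readStudyConfig(config)
  opts <- .studyDefaults(config$options)
  sessions <- config$sessions
  ids <- vapply(sessions, function(s)
    paste(s$subject, s$condition, sep = "/"), "")
  .stopIf(anyDuplicated(ids) > 0, "duplicate (subject, condition) pairs")
  # subject-specific stretch templates: the reference condition's T1
  templates <- list()
  if (isTRUE(opts$computeStretch) && !is.null(opts$referenceCondition)) {
    for (s in sessions) {
      if (identical(as.character(s$condition),
                    as.character(opts$referenceCondition)) &&
          !is.null(s$t1) && file.exists(s$t1))
        templates[[s$subject]] <- readNiftiImage(s$t1)
    }
  }
  allRows <- list(); qcRows <- list()
  for (s in sessions) {
    res <- tryCatch(
      .sessionMetrics(s, opts, templates[[s$subject]]),
      error = function(e) {
        warning("session ", s$subject, "/", s$condition, " failed: ",
                conditionMessage(e))
        list(rows = list(),
             qc = list(subject = s$subject, condition = s$condition,
                       t1Ratio = NA_real_, maxTranslation = NA_real_,
                       maxRotation = NA_real_,
                       error = conditionMessage(e)))
      })
    allRows <- c(allRows, res$rows)
    qcRows[[length(qcRows) + 1L]] <- as.data.frame(res$qc)
  }
  .stopIf(length(allRows) == 0L, "no metrics computed for any session")
  tab <- metricTable(do.call(rbind, allRows))
  nCond <- length(unique(metricData(tab)$condition))
  report <- if (nCond >= 2L) {
    metricReport(tab, referenceCondition = opts$referenceCondition)
  } else {
    warning("single condition: reliability section empty")
    list(summary = NULL, anova = list(), icc = list(), posthoc = list())
  }
  list(table = tab, report = report, qc = do.call(rbind, qcRows))
}

# Per-subject phantom ground truth for the demo study. Subject-level
# variability is programmed (region sizes, tSNR baseline, tensor
# eigenvalues); condition has no programmed effect, so ANOVA should be
# null and ICC high for these metrics.
.demoSubjectTruth <- function(subjSeed, size) {
  .withSeed(subjSeed, {
    thalScale <- stats::runif(1, 0.85, 1.15)
    baseline <- stats::runif(1, 350, 1050)
    l1 <- stats::runif(1, 1.5, 1.9) * 1e-3
    l23 <- stats::runif(1, 0.2, 0.4) * 1e-3
  })
  structDims <- if (size == "tiny") c(20, 20, 20) else c(28, 28, 28)
  boldDims <- if (size == "tiny") c(10, 10, 6) else c(14, 14, 8)
  nVol <- if (size == "tiny") 64L else 120L
  dwiDims <- if (size == "tiny") c(8, 8, 8) else c(10, 10, 10)
  list(
    structural = structuralPhantomSpec(
      dims = structDims, voxelDims = c(2, 2, 2),
      rois = list(list(label = 1L, name = "thalamus", type = "ellipsoid",
                       center = structDims,   # lattice center in mm (2 mm voxels)
                       semiAxes = c(12, 10, 8) * thalScale,
                       intensity = 900)),
      bgNoiseSd = 2, smoothFwhm = 3),
    bold = boldPhantomSpec(
      dims = boldDims, voxelDims = c(3, 3, 3), tr = 2.5, nVolumes = nVol,
      rois = list(list(label = 1L, name = "dmn", type = "ellipsoid",
                       center = boldDims * 3 / 2,
                       semiAxes = boldDims * 3 / 2 * 0.85,
                       baseline = baseline, sharedSd = 1, voxelSd = 2)),
      driftAmplitude = 2, driftPeriod = 300,
      nuisanceAmplitudes = c(1.5, 1)),
    dwi = dwiPhantomSpec(
      dims = dwiDims, voxelDims = c(2, 2, 2),
      regions = list(list(label = 1L, name = "wm", type = "ellipsoid",
                          center = dwiDims, semiAxes = dwiDims * 2 * 0.4,
                          D = diag(c(l1, l23, l23)))),
      s0 = 1000, noiseSd = 5))
}

.demoScheme <- function(nDirs = 12L, nB0 = 2L, b = 1000) {
  # deterministic spiral-ish unit directions
  i <- seq_len(nDirs)
  z <- (2 * i - nDirs - 1) / nDirs
  th <- i * pi * (3 - sqrt(5))
  g <- rbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  diffusionScheme(c(rep(0, nB0), rep(b, nDirs)),
                  cbind(matrix(0, 3, nB0), g))
}

#' Generate and analyze a complete phantom study
#'
#' Builds a full subject x condition phantom study — structural, BOLD
#' and DWI phantoms per session, written as NIfTI / bval / bvec / motion
#' text via the package's own writers, plus a YAML config — and runs
#' [runStudy()] on it. Subject-level variability (region size, tSNR
#' baseline, diffusion eigenvalues) is programmed; conditions differ
#' only in noise realization, so ANOVA across conditions should be null
#' and ICC high for the varying metrics. Deterministic for a fixed
#' seed.
#'
#' @param seed integer RNG seed.
#' @param outdir writable output directory.
#' @param nSubjects,nConditions study layout (default 6 x 3).
#' @param size "small" or "tiny" phantom geometry.
#' @param computeStretch run the per-session affine registrations
#'   (the slowest step).
#' @return The [runStudy()] result, plus `configPath` and `truth`
#'   (per-subject ground truth).
#' @export
demoPhantomStudy <- function(seed = 1, outdir, nSubjects = 6L,
                             nConditions = 3L, size = c("small", "tiny"),
                             computeStretch = TRUE) {
  size <- match.arg(size)
  .stopIf(!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE),
          "cannot create output directory %s", outdir)
  scheme <- .demoScheme()
  sessions <- list()
  truth <- list()
  for (si in seq_len(nSubjects)) {
    subj <- sprintf("sub%02d", si)
    specs <- .demoSubjectTruth(seed * 1000L + si, size)
    truth[[subj]] <- specs
    for (ci in seq_len(nConditions)) {
      cond <- as.character(ci)
      sessSeed <- seed * 100000L + si * 100L + ci
      base <- file.path(outdir, sprintf("%s_con%d", subj, ci))
      st <- makeStructuralPhantom(specs$structural, seed = sessSeed)
      writeNiftiImage(st$image, paste0(base, "_t1.nii.gz"))
      writeNiftiImage(st$labels, paste0(base, "_t1lab.nii.gz"))
      bo <- makeBoldPhantom(specs$bold, seed = sessSeed + 1L)
      writeNiftiImage(bo$bold, paste0(base, "_bold.nii.gz"))
      writeNiftiImage(bo$labels, paste0(base, "_boldroi.nii.gz"))
      writeMotionParams(bo$motion, paste0(base, "_motion.par"))
      utils::write.table(bo$nuisance, paste0(base, "_nuisance.txt"),
                         row.names = FALSE, col.names = FALSE)
      dw <- makeDwiPhantom(specs$dwi, scheme, seed = sessSeed + 2L)
      writeNiftiImage(dw$dwi, paste0(base, "_dwi.nii.gz"))
      writeNiftiImage(dw$labels, paste0(base, "_dwilab.nii.gz"))
      writeBvalsBvecs(scheme, paste0(base, ".bval"), paste0(base, ".bvec"))
      sessions[[length(sessions) + 1L]] <- list(
        subject = subj, condition = cond,
        t1 = paste0(base, "_t1.nii.gz"),
        t1Labels = paste0(base, "_t1lab.nii.gz"),
        bold = paste0(base, "_bold.nii.gz"),
        boldRoi = paste0(base, "_boldroi.nii.gz"),
        motion = paste0(base, "_motion.par"),
        nuisance = paste0(base, "_nuisance.txt"),
        dwi = paste0(base, "_dwi.nii.gz"),
        bval = paste0(base, ".bval"),
        bvec = paste0(base, ".bvec"),
        dwiLabels = paste0(base, "_dwilab.nii.gz"),
        t1RegionNames = list("1" = "thalamus"),
        boldRegionNames = list("1" = "dmn"),
        dwiRegionNames = list("1" = "wm"))
    }
  }
  config <- list(
    options = list(referenceCondition = "2", referenceMean = 1000,
                   fwhm = 5, highpass = 150, discard = 4L,
                   computeStretch = computeStretch,
                   registration = list(levels = c(2L, 1L), sweeps = 2L,
                                       nmIter = 150L)),
    sessions = sessions)
  configPath <- file.path(outdir, "study.yaml")
  yaml::write_yaml(config, configPath)
  res <- runStudy(config)
  res$configPath <- configPath
  res$truth <- truth
  res
}
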