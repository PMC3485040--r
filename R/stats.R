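# Reliability statistics across scanner conditions: one-way ANOVA,
# ANOVA reconstruction from printed summaries, intraclass correlation
# (consistency ICC(3,1)), paired post-hoc t-tests, and the per-metric
# report.

#' One-way ANOVA across conditions
#'
#' Tests group mean differences across conditions with the standard
#' between/within decomposition, p from the F distribution with
#' (k - 1, N - k) degrees of freedom.
#'
#' @param groups a list of numeric vectors (>= 2 groups, each >= 2
#'   values), or a data.frame with columns `value` and `group`.
#' @return An [AnovaResult-class].
#' @export
oneWayAnova <- function(groups) {
  if (is.data.frame(groups))
    groups <- split(groups$value, groups$group)
  .stopIf(length(groups) < 2L, "need at least 2 groups")
  sizes <- lengths(groups)
  .stopIf(any(sizes < 2L), "every group needs at least 2 values")
  value <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), sizes))
  tab <- suppressWarnings(stats::anova(stats::lm(value ~ grp)))
  Fv <- tab[["F value"]][1L]
  if (!is.finite(Fv)) Fv <- 0   # identical group means and zero residual
  new("AnovaResult", F = Fv, dfBetween = tab[["Df"]][1L],
      dfWithin = tab[["Df"]][2L],
      p = stats::pf(Fv, tab[["Df"]][1L], tab[["Df"]][2L],
                    lower.tail = FALSE),
      mode = "one-way")
}

#' One-way ANOVA from printed summaries
#'
#' Reconstructs the balanced one-way ANOVA from per-group means and
#' standard errors, as printed in summary tables: per-group
#' sd = se sqrt(n), MSW = mean of per-group variances,
#' MSB = n sum((mi - mbar)^2) / (k - 1), F = MSB / MSW. Exact for
#' balanced designs.
#'
#' @param means per-group means.
#' @param ses per-group standard errors (> 0).
#' @param nPerGroup common group size.
#' @return An [AnovaResult-class].
#' @examples
#' anovaFromSummary(c(0.44, 0.44, 0.44), c(0.03, 0.04, 0.05), 6)
#' @export
anovaFromSummary <- function(means, ses, nPerGroup) {
  k <- length(means)
  .stopIf(k < 2L, "need at least 2 groups")
  .stopIf(length(ses) != k, "means and ses lengths differ")
  .stopIf(any(ses <= 0), "standard errors must be > 0")
  .stopIf(nPerGroup < 2L, "need n >= 2 per group")
  vars <- (ses * sqrt(nPerGroup))^2
  msw <- mean(vars)
  msb <- nPerGroup * sum((means - mean(means))^2) / (k - 1)
  Fv <- msb / msw
  dfB <- k - 1
  dfW <- k * (nPerGroup - 1)
  new("AnovaResult", F = Fv, dfBetween = dfB, dfWithin = dfW,
      p = stats::pf(Fv, dfB, dfW, lower.tail = FALSE),
      mode = "from-summary")
}

# Two-way (subject x condition) mean squares of a complete n x k matrix.
.twoWayMeanSquares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  subjMeans <- rowMeans(m)
  condMeans <- colMeans(m)
  ssSubj <- k * sum((subjMeans - grand)^2)
  ssCond <- n * sum((condMeans - grand)^2)
  ssTot <- sum((m - grand)^2)
  ssErr <- ssTot - ssSubj - ssCond
  list(bms = ssSubj / (n - 1),
       jms = ssCond / (k - 1),
       ems = ssErr / ((n - 1) * (k - 1)))
}

#' Intraclass correlation (consistency ICC(3,1))
#'
#' Test-retest reliability of a complete subject-by-condition table:
#' ICC = (BMS - EMS) / (BMS + (k - 1) EMS), where BMS is the
#' between-subject mean square and EMS the residual mean square after
#' removing subject and condition effects (Shrout-Fleiss consistency
#' form). Values near 1 mean between-subject differences dominate the
#' condition error; near 0, condition error dominates. The raw value
#' can be negative; the reported value is clipped to [0, 1] with the
#' raw value retained. An all-equal table is flagged undefined.
#'
#' @param table an n x k numeric matrix (subjects x conditions), or a
#'   [MetricTable] holding exactly one metric.
#' @return An [IccResult-class].
#' @export
iccConsistency <- function(table) {
  m <- .asSubjectConditionMatrix(table)
  .stopIf(nrow(m) < 2L || ncol(m) < 2L,
          "need at least 2 subjects and 2 conditions")
  .stopIf(anyNA(m), "incomplete table: every (subject, condition) cell is required")
  ms <- .twoWayMeanSquares(m)
  k <- ncol(m)
  if (ms$bms <= 0 && ms$ems <= 0) {
    return(new("IccResult", icc = NA_real_, iccRaw = NA_real_,
               bms = ms$bms, ems = ms$ems, k = as.integer(k),
               defined = FALSE))
  }
  raw <- (ms$bms - ms$ems) / (ms$bms + (k - 1) * ms$ems)
  new("IccResult", icc = min(max(raw, 0), 1), iccRaw = raw,
      bms = ms$bms, ems = ms$ems, k = as.integer(k), defined = TRUE)
}

.asSubjectConditionMatrix <- function(table) {
  if (is(table, "MetricTable")) {
    d <- metricData(table)
    .stopIf(length(unique(d$metric)) != 1L,
            "table holds %d metrics; supply one", length(unique(d$metric)))
    m <- tapply(d$value, list(d$subject, d$condition), mean)
    return(m)
  }
  as.matrix(table)
}

#' Paired t-test between two conditions
#'
#' Post-hoc comparison of two conditions over the same subjects: t on
#' the paired differences, two-sided p with n - 1 degrees of freedom.
#' Zero difference variance is an error.
#'
#' @param conditionA,conditionB equal-length paired numeric vectors.
#' @return A list with `t`, `p`, `df`.
#' @export
pairedTtest <- function(conditionA, conditionB) {
  .stopIf(length(conditionA) != length(conditionB),
          "paired vectors must have equal length")
  .stopIf(length(conditionA) < 2L, "need at least 2 pairs")
  d <- conditionA - conditionB
  .stopIf(stats::sd(d) == 0,
          "zero difference variance; paired t undefined")
  res <- stats::t.test(conditionA, conditionB, paired = TRUE)
  list(t = unname(res$statistic), p = res$p.value,
       df = unname(res$parameter))
}

#' Per-metric reliability report
#'
#' For every metric in a [MetricTable]: per-condition mean and standard
#' error, one-way ANOVA across conditions, ICC(3,1), and (optionally)
#' paired t-tests of every other condition against a reference
#' condition. Metrics with an incomplete subject-by-condition crossing
#' get a warning and no ICC.
#'
#' @param table a [MetricTable].
#' @param referenceCondition optional condition id for post-hoc paired
#'   comparisons.
#' @return A list with `summary` (data.frame: metric, condition, mean,
#'   se, n), `anova`, `icc`, and `posthoc` (lists keyed by metric).
#' @export
metricReport <- function(table, referenceCondition = NULL) {
  stopifnot(is(table, "MetricTable"))
  d <- metricData(table)
  metrics <- unique(d$metric)
  conds <- sort(unique(d$condition))
  summ <- do.call(rbind, lapply(metrics, function(met) {
    dm <- d[d$metric == met, ]
    do.call(rbind, lapply(conds, function(co) {
      v <- dm$value[dm$condition == co]
      data.frame(metric = met, condition = co, mean = mean(v),
                 se = stats::sd(v) / sqrt(length(v)), n = length(v))
    }))
  }))
  anovas <- list(); iccs <- list(); posthoc <- list()
  for (met in metrics) {
    dm <- d[d$metric == met, ]
    groups <- split(dm$value, dm$condition)
    anovas[[met]] <- if (length(groups) >= 2L && all(lengths(groups) >= 2L))
      oneWayAnova(groups) else NULL
    wide <- tapply(dm$value, list(dm$subject, dm$condition), mean)
    if (anyNA(wide) || ncol(wide) < 2L || nrow(wide) < 2L) {
      warning("metric '", met,
              "' has an incomplete subject x condition crossing; ICC skipped")
    } else {
      iccs[[met]] <- iccConsistency(wide)
      if (!is.null(referenceCondition) &&
          referenceCondition %in% colnames(wide)) {
        ph <- list()
        for (co in setdiff(colnames(wide), referenceCondition)) {
          ph[[co]] <- tryCatch(
            pairedTtest(wide[, co], wide[, referenceCondition]),
            error = function(e) NULL)
        }
        posthoc[[met]] <- ph
      }
    }
  }
  list(summary = summ, anova = anovas, icc = iccs, posthoc = posthoc)
}
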