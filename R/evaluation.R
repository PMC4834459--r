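#' Confusion-matrix metrics of a cross-validated classifier
#'
#' Patients are the positive class: sensitivity is the correct rate among
#' patients, specificity among controls.
#'
#' @param result a \linkS4class{CVResult}.
#' @return a \linkS4class{MetricsReport} (AUC left NA; see
#'   \code{\link{rocCurveAUC}} or \code{\link{evaluateCVResult}}).
#' @export
confusionMetrics <- function(result) {
  truth <- result@trueLabels
  pred <- result@predictions
  tp <- sum(truth == "patient" & pred == "patient")
  fn <- sum(truth == "patient" & pred == "control")
  tn <- sum(truth == "control" & pred == "control")
  fp <- sum(truth == "control" & pred == "patient")
  n <- tp + fn + tn + fp
  new("MetricsReport",
      tp = tp, fn = fn, tn = tn, fp = fp,
      accuracy = (tp + tn) / n,
      sensitivity = tp / (tp + fn),
      specificity = tn / (tn + fp),
      auc = NA_real_, pBinomial = NA_real_,
      rocPoints = matrix(numeric(0), ncol = 2,
                         dimnames = list(NULL, c("FPR", "TPR"))),
      notes = list(positiveClass = "patient"))
}

#' ROC curve and exact rank-based AUC
#'
#' The curve sweeps a threshold over the sorted unique decision values with
#' the rule \code{z > tau}; the AUC is the rank statistic
#' \code{P(z_patient > z_control) + P(tie)/2}, computed exactly via midranks.
#'
#' @param decisionValues numeric vector.
#' @param labels labels (levels control/patient).
#' @return list with \code{rocPoints} (matrix FPR, TPR from (0,0) to (1,1)),
#'   \code{auc}, and \code{warning} (set when decision values are constant,
#'   in which case auc = 0.5).
#' @export
rocCurveAUC <- function(decisionValues, labels) {
  y <- as_group_factor(labels)
  pos <- y == "patient"; neg <- !pos
  nP <- sum(pos); nC <- sum(neg)
  if (nP == 0L || nC == 0L) stop("both classes must be present")
  warn <- NULL
  if (length(unique(decisionValues)) == 1L)
    warn <- "constant decision values: AUC set to 0.5"
  thr <- sort(unique(decisionValues), decreasing = TRUE)
  pts <- t(vapply(c(Inf, thr), function(tau) {
    c(FPR = sum(decisionValues[neg] > tau) / nC,
      TPR = sum(decisionValues[pos] > tau) / nP)
  }, numeric(2)))
  pts <- rbind(pts, c(1, 1))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  # midrank (Mann-Whitney) AUC: exact, ties counted half
  rk <- rank(decisionValues)
  u <- sum(rk[pos]) - nP * (nP + 1) / 2
  auc <- if (is.null(warn)) u / (nP * nC) else 0.5
  list(rocPoints = pts, auc = auc, warning = warn)
}

#' One-sided exact binomial test against chance
#'
#' Upper-tail probability of observing at least \code{kCorrect} successes in
#' \code{n} Bernoulli(p0) trials.
#'
#' @param kCorrect number of correctly classified subjects.
#' @param n total subjects.
#' @param p0 chance level (default 0.5).
#' @return the exact one-sided p-value.
#' @export
binomialVsChance <- function(kCorrect, n, p0 = 0.5) {
  stopifnot(kCorrect >= 0, kCorrect <= n)
  stats::binom.test(kCorrect, n, p0, alternative = "greater")$p.value
}

#' Pearson correlation between decision values and a covariate
#'
#' Standard product-moment correlation with the t-transform p-value
#' (\code{stats::cor.test}); missing covariate values are dropped pairwise
#' and the dropped count reported.
#'
#' @param result a \linkS4class{CVResult} (or numeric decision values).
#' @param scores numeric covariate (e.g. symptom severity), may contain NA.
#' @return list with \code{r}, \code{p}, \code{nUsed}, \code{nDropped}.
#' @export
correlateDecisions <- function(result, scores) {
  z <- if (is(result, "CVResult")) result@decisionValues else result
  if (length(z) != length(scores))
    stop("scores must have one value per subject")
  ok <- !is.na(z) & !is.na(scores)
  if (sum(ok) < 3L) stop("need at least 3 paired non-missing values")
  if (stats::sd(z[ok]) == 0 || stats::sd(scores[ok]) == 0)
    stop("zero variance in decision values or scores")
  ct <- stats::cor.test(z[ok], scores[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       nUsed = sum(ok), nDropped = sum(!ok))
}

#' Rank-sum comparison of decision values between two subgroups
#'
#' Reports the Mann-Whitney U of the first subgroup (the rank sum of that
#' subgroup minus \code{n1 (n1 + 1) / 2}, midranks for ties) alongside the
#' raw rank sum, since software conventions differ. The p-value is exact
#' when the samples are small and untied, otherwise a normal approximation
#' with tie and continuity correction (\code{stats::wilcox.test}).
#'
#' @param values numeric (e.g. patients' decision values).
#' @param groupFlags logical or two-level vector; TRUE / first level defines
#'   the first subgroup.
#' @param alternative passed to \code{wilcox.test} (default two-sided).
#' @return list with \code{W} (U statistic of the first subgroup),
#'   \code{rankSum}, \code{p}, \code{n1}, \code{n2}.
#' @export
ranksumByGroup <- function(values, groupFlags, alternative = "two.sided") {
  g <- if (is.logical(groupFlags)) factor(ifelse(groupFlags, "g1", "g2"),
                                          levels = c("g1", "g2"))
       else factor(groupFlags)
  if (nlevels(g) != 2L || any(table(g) == 0L))
    stop("both subgroups must be non-empty")
  x <- values[g == levels(g)[1]]
  yv <- values[g == levels(g)[2]]
  n1 <- length(x); n2 <- length(yv)
  exact <- (n1 + n2 <= 12) && !any(duplicated(values))
  wt <- suppressWarnings(stats::wilcox.test(x, yv, alternative = alternative,
                                            exact = exact, correct = TRUE))
  rk <- rank(c(x, yv))
  rankSum <- sum(rk[seq_len(n1)])
  list(W = unname(wt$statistic), rankSum = rankSum, p = wt$p.value,
       n1 = n1, n2 = n2)
}

#' Full evaluation of a cross-validated classifier
#'
#' Confusion metrics, ROC/AUC, and the exact binomial test against chance in
#' one report. A chi-square test on the 2x2 confusion table is included in
#' the notes as a separately named output.
#'
#' @param result a \linkS4class{CVResult}.
#' @return a \linkS4class{MetricsReport}.
#' @export
evaluateCVResult <- function(result) {
  rep_ <- confusionMetrics(result)
  roc <- rocCurveAUC(result@decisionValues, result@trueLabels)
  rep_@auc <- roc$auc
  rep_@rocPoints <- roc$rocPoints
  k <- rep_@tp + rep_@tn
  n <- k + rep_@fn + rep_@fp
  rep_@pBinomial <- binomialVsChance(k, n)
  notes <- rep_@notes
  notes$binomialAlternative <- "one-sided, upper tail, p0 = 0.5"
  conf <- matrix(c(rep_@tp, rep_@fn, rep_@fp, rep_@tn), 2)
  notes$chisqConfusionP <- tryCatch(
    suppressWarnings(stats::chisq.test(conf)$p.value), error = function(e) NA_real_)
  if (!is.null(roc$warning)) notes$rocWarning <- roc$warning
  rep_@notes <- notes
  rep_
}

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport: accuracy %.2f%% (tp %d, fn %d, tn %d, fp %d)\n",
              100 * object@accuracy, object@tp, object@fn, object@tn, object@fp))
  cat(sprintf("  sensitivity %.2f%%, specificity %.2f%%\n",
              100 * object@sensitivity, 100 * object@specificity))
  if (!is.na(object@auc))
    cat(sprintf("  AUC %.3f; binomial p vs chance %.3g\n",
                object@auc, object@pBinomial))
})

#' Serialize a MetricsReport to a plain list / JSON
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path optional JSON output path.
#' @return named list (invisibly when writing).
#' @export
metricsAsList <- function(report, path = NULL) {
  out <- list(
    tp = report@tp, fn = report@fn, tn = report@tn, fp = report@fp,
    accuracy = report@accuracy, sensitivity = report@sensitivity,
    specificity = report@specificity, auc = report@auc,
    p_binomial = report@pBinomial,
    roc_points = unname(apply(report@rocPoints, 1, as.numeric, simplify = FALSE)),
    notes = report@notes)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
    return(invisible(out))
  }
  out
}
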