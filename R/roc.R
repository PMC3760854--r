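#' Residue-level ROC curve
#'
#' Sweeps the decision threshold from above the highest score down to below
#' the lowest (a positive call is `score >= threshold`, closed) and records
#' the true and false positive rates `TPR = TP / (TP + FN)`,
#' `FPR = FP / (FP + TN)` at the sorted unique scores plus sentinels, so the
#' curve starts at (0, 0) and ends at (1, 1). The trapezoidal area under the
#' curve is attached; it equals the Mann-Whitney pairwise probability that a
#' random positive outranks a random negative, with ties counted half.
#'
#' @param scores numeric predictions (conventionally in [0, 1])
#' @param labels binary labels, same length; both classes must be present
#' @return a [ROCCurve-class]
#' @export
rocPoints <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary", call. = FALSE)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to draw a ROC curve", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  # counts of positives/negatives at each unique score, accumulated downwards
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tpAt <- cumsum(y)[!duplicated(grp, fromLast = TRUE)]
  fpAt <- cumsum(1L - y)[!duplicated(grp, fromLast = TRUE)]
  tpr <- c(0, tpAt / nPos, 1)
  fpr <- c(0, fpAt / nNeg, 1)
  a <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  new("ROCCurve", thresholds = thr, fpr = fpr, tpr = tpr,
      auc = min(max(a, 0), 1))
}

#' AUC directly from scores and labels
#'
#' Convenience wrapper: [rocPoints()] followed by [auc()].
#'
#' @inheritParams rocPoints
#' @return numeric(1) in [0, 1]; 0.5 is a random ranking, 1 a perfect one
#' @export
aucFromScores <- function(scores, labels) auc(rocPoints(scores, labels))

#' Write a ROC curve as TSV
#'
#' One row per threshold (`threshold`, `fpr`, `tpr`), followed by a comment
#' line carrying the AUC.
#'
#' @param curve a [ROCCurve-class]
#' @param path output path
#' @return `path`, invisibly
#' @export
writeROC <- function(curve, path) {
  stopifnot(is(curve, "ROCCurve"))
  df <- rocTable(curve)
  con <- file(path, "w"); on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# AUC\t%.6f", curve@auc), con)
  invisible(path)
}
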