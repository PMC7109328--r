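#' Classification metrics from confusion counts
#'
#' Computes total accuracy (ACC), sensitivity (SN, true-positive rate),
#' specificity (SP, true-negative rate) and the Matthews correlation
#' coefficient (MCC) from the four confusion-matrix counts:
#' \deqn{ACC = (TP+TN)/(TP+TN+FP+FN)}
#' \deqn{SN = TP/(TP+FN), \quad SP = TN/(TN+FP)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}
#' A metric whose denominator is zero (e.g. sensitivity with no positives in
#' the evaluated set) is reported as 0 and flagged as undefined rather than
#' raising, so aggregation over many splits never aborts.
#'
#' @param tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives
#' @return a list with `acc`, `sn`, `sp`, `mcc`, the counts, `n` and
#'   `undefined` (character vector naming any zero-denominator metrics)
#' @examples
#' compute_metrics(tp = 50, tn = 40, fp = 10, fn = 0)
#' @export
compute_metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop_validation("confusion counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop_validation("no evaluated samples (all counts zero)")
  undefined <- character(0)
  safe_div <- function(num, den, name) {
    if (den == 0) { undefined <<- c(undefined, name); 0 } else num / den
  }
  acc <- (tp + tn) / n
  sn <- safe_div(tp, tp + fn, "sn")
  sp <- safe_div(tn, tn + fp, "sp")
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) { undefined <- c(undefined, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  list(acc = acc, sn = sn, sp = sp, mcc = mcc,
       tp = tp, tn = tn, fp = fp, fn = fn, n = n, undefined = undefined)
}

#' ROC curve and AUC from scores
#'
#' Sweeps a decision threshold over the unique scores in descending order
#' (ties grouped into a single step), producing the ROC curve from (0,0) to
#' (1,1), and integrates it with the trapezoidal rule. With ties handled this
#' way the area equals the Mann-Whitney probability estimate
#' P(score+ > score-) + 0.5 P(score+ = score-).
#'
#' @param score numeric vector of classifier scores (higher = more positive)
#' @param label labels, coerced to logical positives via `label == positive`
#' @param positive value of `label` denoting the positive class
#' @return a list with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`
#' @examples
#' compute_roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), positive = 1)$auc
#' @export
compute_roc_auc <- function(score, label, positive = "positive") {
  if (length(score) != length(label))
    stop_validation("score and label lengths differ")
  pos <- label == positive
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop_validation("ROC requires both classes present")
  ord <- order(score, decreasing = TRUE)
  s <- score[ord]
  p <- pos[ord]
  # group tied scores into one threshold step
  grp_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  roc <- data.frame(threshold = c(Inf, s[grp_end]), fpr = fpr, tpr = tpr)
  list(roc = roc, auc = auc)
}

#' Aggregate evaluation reports
#'
#' Averages metrics across reports weighted by each report's evaluated sample
#' count, as in multi-split benchmarks where every balanced training set
#' yields one report. Per-report values are retained for dispersion.
#'
#' @param reports list of `evaluation_report` objects from the same
#'   classifier family
#' @return an `evaluation_report` with `level = "overall"`; elements `acc`,
#'   `sn`, `sp`, `mcc`, `auc` are weighted means, `per_report` holds the
#'   individual values
#' @export
aggregate_reports <- function(reports) {
  if (length(reports) == 0L) stop_validation("no reports to aggregate")
  stopifnot(all(vapply(reports, inherits, logical(1), "evaluation_report")))
  fam <- unique(vapply(reports, `[[`, character(1), "family"))
  if (length(fam) > 1L)
    stop_validation("cannot aggregate across classifier families: %s",
                    paste(fam, collapse = ", "))
  w <- vapply(reports, `[[`, numeric(1), "n")
  wmean <- function(field) {
    v <- vapply(reports, function(r) r[[field]] %||% NA_real_, numeric(1))
    if (all(is.na(v))) NA_real_ else sum(w * v, na.rm = TRUE) / sum(w[!is.na(v)])
  }
  per <- data.frame(
    n = w,
    acc = vapply(reports, `[[`, numeric(1), "acc"),
    sn = vapply(reports, `[[`, numeric(1), "sn"),
    sp = vapply(reports, `[[`, numeric(1), "sp"),
    mcc = vapply(reports, `[[`, numeric(1), "mcc"),
    auc = vapply(reports, function(r) r$auc %||% NA_real_, numeric(1))
  )
  out <- list(family = fam, level = "overall", n = sum(w),
              acc = wmean("acc"), sn = wmean("sn"), sp = wmean("sp"),
              mcc = wmean("mcc"), auc = wmean("auc"),
              per_report = per,
              undefined = unique(unlist(lapply(reports, `[[`, "undefined"))))
  class(out) <- "evaluation_report"
  out
}

new_evaluation_report <- function(family, level, metrics, auc = NULL,
                                  roc = NULL, folds = NULL, scores = NULL) {
  out <- list(family = family, level = level, n = metrics$n,
              acc = metrics$acc, sn = metrics$sn, sp = metrics$sp,
              mcc = metrics$mcc,
              tp = metrics$tp, tn = metrics$tn, fp = metrics$fp,
              fn = metrics$fn,
              auc = auc, roc = roc, folds = folds, scores = scores,
              undefined = metrics$undefined)
  class(out) <- "evaluation_report"
  out
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("evaluation_report [%s, %s] on %d samples\n",
              x$family, x$level, x$n))
  fmt <- function(v) if (is.null(v) || is.na(v)) "NA" else format(round(v, digits))
  cat(sprintf("  ACC %s  SN %s  SP %s  MCC %s  AUC %s\n",
              fmt(x$acc), fmt(x$sn), fmt(x$sp), fmt(x$mcc), fmt(x$auc)))
  if (length(x$undefined))
    cat("  undefined-by-convention (reported as 0):",
        paste(unique(x$undefined), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.evaluation_report <- function(object, ...) {
  print(object, ...)
  if (!is.null(object$per_report)) {
    cat("per-report dispersion:\n")
    print(round(apply(object$per_report[-1], 2, stats::sd), 4))
  }
  invisible(object)
}

#' Plot an evaluation report's ROC curve
#'
#' @param x an `evaluation_report` carrying a ROC curve
#' @param ... passed to [graphics::plot()]
#' @export
plot.evaluation_report <- function(x, ...) {
  if (is.null(x$roc)) stop_validation("report carries no ROC curve")
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("%s (AUC = %.3f)", x$family, x$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report an `evaluation_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  out <- report[c("family", "level", "n", "acc", "sn", "sp", "mcc", "auc",
                  "tp", "tn", "fp", "fn", "undefined")]
  out <- out[!vapply(out, is.null, logical(1))]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a ROC curve to TSV
#'
#' Columns `fpr`, `tpr`, `threshold`.
#'
#' @param report an `evaluation_report` carrying a ROC curve
#' @param path output path
#' @return `path`, invisibly
#' @export
write_roc_tsv <- function(report, path) {
  if (is.null(report$roc)) stop_validation("report carries no ROC curve")
  utils::write.table(report$roc[, c("fpr", "tpr", "threshold")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
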