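# Confusion-matrix construction and derived statistics, with STP as the
# positive class throughout.

# canonicalize labels to logical "is STP"
.as_positive <- function(x) {
  if (is.logical(x)) return(x)
  if (is.factor(x)) x <- as.character(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(x == 1)
  }
  u <- unique(x)
  if (!all(u %in% c("STP", "non-STP")))
    stop("character labels must be 'STP'/'non-STP'", call. = FALSE)
  x == "STP"
}

#' Build a 2x2 confusion matrix
#'
#' @param truth,predicted Binary label vectors of equal length: logical,
#'   0/1 numeric, or `"STP"`/`"non-STP"` character/factor. STP (TRUE, 1) is
#'   the positive class.
#' @return Object of class `stp_confusion`: named integer vector
#'   `c(TP, FP, TN, FN)`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length", call. = FALSE)
  t <- .as_positive(truth); p <- .as_positive(predicted)
  structure(c(TP = sum(t & p), FP = sum(!t & p),
              TN = sum(!t & !p), FN = sum(t & !p)),
            class = "stp_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total` and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A zero denominator makes that metric `NaN` with a warning; it is never
#' silently reported as 0.
#'
#' @param cm An `stp_confusion`, or a named vector with elements TP, FP,
#'   TN, FN.
#' @return Named numeric vector `c(sensitivity, specificity, precision,
#'   accuracy, mcc)`.
#' @export
classification_metrics <- function(cm) {
  cm <- as.numeric(cm[c("TP", "FP", "TN", "FN")])
  if (anyNA(cm) || any(cm < 0)) stop("need non-negative TP/FP/TN/FN", call. = FALSE)
  TP <- cm[1]; FP <- cm[2]; TN <- cm[3]; FN <- cm[4]
  if (TP + FP + TN + FN == 0) stop("empty confusion matrix", call. = FALSE)
  div <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (zero denominator)", call. = FALSE); NaN }
    else num / den
  }
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(sensitivity = div(TP, TP + FN, "sensitivity"),
    specificity = div(TN, TN + FP, "specificity"),
    precision   = div(TP, TP + FP, "precision"),
    accuracy    = (TP + TN) / (TP + FP + TN + FN),
    mcc         = div(TP * TN - FP * FN, mcc_den, "MCC"))
}

#' Receiver operating characteristic curve
#'
#' Sweeps the decision threshold over the unique scores (higher score =
#' more STP-like), grouping tied scores into a single step.
#'
#' @param scores Numeric decision values.
#' @param truth Binary truth labels (see [confusion_matrix()]).
#' @return data.frame with columns `threshold`, `fpr`, `tpr`, starting at
#'   (0, 0) and ending at (1, 1).
#' @export
roc_curve <- function(scores, truth) {
  t <- .as_positive(truth)
  if (length(scores) != length(t))
    stop("scores and truth differ in length", call. = FALSE)
  npos <- sum(t); nneg <- sum(!t)
  if (npos == 0 || nneg == 0)
    stop("ROC needs at least one positive and one negative", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- t[o]
  grp <- cumsum(!duplicated(s))           # tie groups in descending order
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / nneg),
             tpr = c(0, tp[last] / npos))
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the tie-grouped ROC of [roc_curve()].
#'
#' @inheritParams roc_curve
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, truth) {
  r <- roc_curve(scores, truth)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}
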