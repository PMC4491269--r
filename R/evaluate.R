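# Evaluation protocols: repeated random subsampling (the 100/300 x 200
# iteration protocol the model family was developed with) and stratified
# k-fold cross-validation. Both report pooled-confusion-matrix metrics;
# subsampling additionally reports per-iteration means and sds.

#' Evaluate the STP classifier under a resampling protocol
#'
#' `protocol = "subsample"`: at each iteration a training set of
#' `n_pos_sample` positives and `n_neg_sample` negatives is drawn without
#' replacement, a fresh model (including fresh normalization constants) is
#' fitted on it, and the complement is scored. Confusion counts are pooled
#' over iterations and per-iteration metrics are summarized as mean +/- sd.
#'
#' `protocol = "kfold"`: stratified k folds; each fold is scored by a model
#' trained on the other k-1, and the pooled confusion matrix is reported.
#'
#' ROC/AUC always come from the pooled held-out decision values.
#'
#' @param pos,neg Named character vectors of positive/negative sequences.
#' @param feature_set,gamma,cost,scale_features Passed to [stp_fit()].
#' @param protocol `"subsample"` (default) or `"kfold"`.
#' @param n_pos_sample,n_neg_sample Training draws per subsampling
#'   iteration (defaults 100 and 300).
#' @param iterations Number of subsampling iterations (default 200).
#' @param k Number of folds for `"kfold"` (default 10).
#' @param seed Integer seed; the whole protocol is reproducible given it.
#' @return Object of class `stp_eval` with elements `protocol`, `pooled`
#'   (confusion counts), `pooled_metrics`, `iteration_metrics` (data.frame,
#'   subsample only), `metric_mean`, `metric_sd`, `roc`, `auc`, `scores`,
#'   `truth`, and the configuration used.
#' @export
stp_evaluate <- function(pos, neg, feature_set = 6L, gamma = 0.1, cost = 0.1,
                         scale_features = TRUE,
                         protocol = c("subsample", "kfold"),
                         n_pos_sample = 100L, n_neg_sample = 300L,
                         iterations = 200L, k = 10L, seed = NULL) {
  protocol <- match.arg(protocol)
  pos <- validate_peptides(pos); neg <- validate_peptides(neg)
  if (!is.null(seed)) set.seed(seed)

  # featurization pieces that do not depend on the training draw
  raw_pos <- .raw_features(pos); raw_neg <- .raw_features(neg)
  raw <- rbind(raw_pos, raw_neg)
  is_pos <- rep(c(TRUE, FALSE), c(length(pos), length(neg)))
  y_all <- factor(ifelse(is_pos, "STP", "non-STP"), levels = c("STP", "non-STP"))

  fit_and_score <- function(train_idx, test_idx) {
    # normalization constants from the training positives carrying a motif
    tr_pos <- train_idx[is_pos[train_idx]]
    ok <- tr_pos[raw$valid[tr_pos]]
    if (length(ok) == 0L)
      stop("no valid motif among sampled training positives", call. = FALSE)
    params <- structure(c(meanP1 = mean(raw$P1[ok]), meanP2 = mean(raw$P2[ok]),
                          meanP3 = mean(raw$P3[ok])), class = "stp_norm")
    X <- .feature_matrix_raw(raw, feature_set, params)
    model <- .fit_on_features(X[train_idx, , drop = FALSE], y_all[train_idx],
                              params, feature_set, gamma, cost, scale_features)
    scores <- .decision_values(model$svm,
                               .apply_scaling(X[test_idx, , drop = FALSE],
                                              model$scaling))
    list(scores = scores, truth = is_pos[test_idx])
  }

  all_scores <- numeric(0); all_truth <- logical(0)
  pooled <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  iter_metrics <- NULL

  if (protocol == "subsample") {
    if (n_pos_sample > length(pos) || n_neg_sample > length(neg))
      stop("protocol asks for more training samples than available",
           call. = FALSE)
    if (n_pos_sample == length(pos) && n_neg_sample == length(neg))
      stop("no held-out sequences remain under this protocol", call. = FALSE)
    rows <- vector("list", iterations)
    for (it in seq_len(iterations)) {
      tr <- c(sample(which(is_pos), n_pos_sample),
              sample(which(!is_pos), n_neg_sample))
      te <- setdiff(seq_along(is_pos), tr)
      r <- fit_and_score(tr, te)
      cm <- confusion_matrix(r$truth, r$scores > 0)
      pooled <- pooled + unclass(cm)
      rows[[it]] <- suppressWarnings(classification_metrics(cm))
      all_scores <- c(all_scores, r$scores); all_truth <- c(all_truth, r$truth)
    }
    iter_metrics <- as.data.frame(do.call(rbind, rows))
  } else {
    if (k < 2L || k > min(length(pos), length(neg)))
      stop("k must be between 2 and the size of the smaller class",
           call. = FALSE)
    fold <- integer(length(is_pos))
    fold[is_pos] <- sample(rep_len(seq_len(k), sum(is_pos)))
    fold[!is_pos] <- sample(rep_len(seq_len(k), sum(!is_pos)))
    for (f in seq_len(k)) {
      te <- which(fold == f); tr <- which(fold != f)
      r <- fit_and_score(tr, te)
      pooled <- pooled + unclass(confusion_matrix(r$truth, r$scores > 0))
      all_scores <- c(all_scores, r$scores); all_truth <- c(all_truth, r$truth)
    }
  }

  pooled <- structure(pooled, class = "stp_confusion")
  structure(list(
    protocol = protocol,
    pooled = pooled,
    pooled_metrics = suppressWarnings(classification_metrics(pooled)),
    iteration_metrics = iter_metrics,
    metric_mean = if (!is.null(iter_metrics))
      colMeans(iter_metrics, na.rm = TRUE),
    metric_sd = if (!is.null(iter_metrics))
      apply(iter_metrics, 2, stats::sd, na.rm = TRUE),
    roc = roc_curve(all_scores, all_truth),
    auc = roc_auc(all_scores, all_truth),
    scores = all_scores, truth = all_truth,
    config = list(feature_set = as.integer(feature_set), gamma = gamma,
                  cost = cost, scale_features = scale_features,
                  n_pos_sample = n_pos_sample, n_neg_sample = n_neg_sample,
                  iterations = iterations, k = k, seed = seed,
                  n_pos = length(pos), n_neg = length(neg))
  ), class = "stp_eval")
}

#' @export
print.stp_eval <- function(x, digits = 4, ...) {
  cat(sprintf("STP classifier evaluation (%s protocol)\n", x$protocol))
  cfg <- x$config
  if (x$protocol == "subsample")
    cat(sprintf("  %d iterations, %d/%d training draws from %d STP / %d non-STP chains\n",
                cfg$iterations, cfg$n_pos_sample, cfg$n_neg_sample,
                cfg$n_pos, cfg$n_neg))
  else
    cat(sprintf("  %d stratified folds over %d STP / %d non-STP chains\n",
                cfg$k, cfg$n_pos, cfg$n_neg))
  cat("  pooled confusion: ",
      paste(names(x$pooled), unclass(x$pooled), sep = "=", collapse = " "),
      "\n", sep = "")
  pm <- round(x$pooled_metrics, digits)
  cat("  pooled metrics:   ",
      paste(names(pm), pm, sep = "=", collapse = " "), "\n", sep = "")
  if (!is.null(x$metric_mean)) {
    cat("  per-iteration mean +/- sd:\n")
    for (m in names(x$metric_mean))
      cat(sprintf("    %-12s %.*f +/- %.*f\n", m, digits, x$metric_mean[[m]],
                  digits, x$metric_sd[[m]]))
  }
  cat(sprintf("  AUC (pooled held-out scores): %.*f\n", digits, x$auc))
  invisible(x)
}

#' @export
summary.stp_eval <- function(object, ...) print(object, ...)

#' Plot the pooled ROC curve of an evaluation
#'
#' @param x An `stp_eval`.
#' @param ... Further arguments to [graphics::plot()].
#' @export
plot.stp_eval <- function(x, ...) {
  graphics::plot(x$roc$fpr, x$roc$tpr, type = "l", xlim = c(0, 1),
                 ylim = c(0, 1), xlab = "False positive rate",
                 ylab = "True positive rate",
                 main = sprintf("ROC (%s protocol), AUC = %.3f",
                                x$protocol, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}
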