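# Independent brute-force implementations used as oracles. These apply the
# grammar/metric definitions literally and share no code with the package
# internals.

oracle_scan <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  cys <- which(chars == "C")
  n <- length(cys)
  if (n < 6)
    return(list(valid = FALSE, reason = "fewer_than_six_cysteines"))
  gaps <- integer(n - 1)
  for (i in seq_len(n - 1)) gaps[i] <- cys[i + 1] - cys[i] - 1
  gmin <- min(gaps)
  k <- which(gaps == gmin)[1]          # leftmost minimum
  if (gmin > 3)
    return(list(valid = FALSE, reason = "min_loop_gt_three"))
  # role the minimum pair plays inside the six-cysteine window
  if (n == 6) {
    role <- k                          # the window is the whole chain
  } else {
    n_downstream <- n - (k + 1)
    role <- if (n_downstream >= 2) 3 else if (n_downstream == 1) 4 else 5
  }
  first <- k - role + 1
  if (first < 1)
    return(list(valid = FALSE, reason = "cannot_anchor"))
  win <- cys[first:(first + 5)]
  wg <- integer(5)
  for (i in 1:5) wg[i] <- win[i + 1] - win[i] - 1
  wm <- which(wg == min(wg))[1]
  if (wm <= 2)
    return(list(valid = FALSE, reason = "min_loop_in_first_two",
                positions = win))
  list(valid = TRUE, reason = "none", positions = win, loops = wg,
       min_loop_index = wm)
}

expect_scan_matches_oracle <- function(seq) {
  got <- scan_motif(seq)
  want <- oracle_scan(seq)
  expect_identical(got$valid, want$valid, info = seq)
  expect_identical(got$reject_reason, want$reason, info = seq)
  if (want$valid) {
    expect_identical(got$positions, as.integer(want$positions), info = seq)
    expect_identical(got$loops, as.integer(want$loops), info = seq)
    expect_identical(got$min_loop_index, as.integer(want$min_loop_index),
                     info = seq)
  }
}

# brute-force metric recomputation: expand counts to label vectors and use
# cross-tabulation plus the phi coefficient (= MCC for binary labels)
oracle_metrics <- function(TP, FP, TN, FN) {
  truth <- rep(c(1, 1, 0, 0), c(TP, FN, TN, FP))
  pred <- rep(c(1, 0, 0, 1), c(TP, FN, TN, FP))
  sens <- if (TP + FN > 0) mean(pred[truth == 1] == 1) else NaN
  spec <- if (TN + FP > 0) mean(pred[truth == 0] == 0) else NaN
  prec <- if (TP + FP > 0) mean(truth[pred == 1] == 1) else NaN
  acc <- mean(truth == pred)
  mcc <- suppressWarnings(stats::cor(truth, pred))  # NA when a margin is constant
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = acc, mcc = if (is.na(mcc)) NaN else mcc)
}
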