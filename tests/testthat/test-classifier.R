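test_that("a separable synthetic problem is fit perfectly and deterministically", {
  pos <- simulate_positives(30, seed = 5)
  neg <- simulate_negatives(40, seed = 5)
  fit <- stp_fit(pos, neg)
  expect_s3_class(fit, "stp_model")
  expect_equal(fit$train_accuracy, 1.0)

  probe <- c(simulate_positives(10, seed = 6), simulate_negatives(10, seed = 6))
  p1 <- predict(fit, probe)
  p2 <- predict(stp_fit(pos, neg), probe)
  expect_identical(p1, p2)

  # labels follow the sign of the margin
  expect_identical(p1$label, ifelse(p1$score > 0, "STP", "non-STP"))
  # training positives from a separable fit come back as STP
  expect_true(all(predict(fit, pos)$label == "STP"))
})

test_that("predict handles empty input and invalid sequences", {
  fit <- stp_fit(simulate_positives(15, seed = 2),
                 simulate_negatives(15, seed = 2))
  out <- predict(fit, character(0))
  expect_identical(nrow(out), 0L)
  expect_identical(names(out), c("id", "label", "score"))
  expect_error(predict(fit, c(bad = "MK7V")), "illegal residue")
  expect_error(stp_fit(character(0), simulate_negatives(5, seed = 1)),
               "non-empty")
})

test_that("identical classes carry no signal: balanced probe accuracy near chance", {
  seqs <- simulate_positives(40, seed = 31)
  fit <- stp_fit(seqs, stats::setNames(seqs, paste0("n", seq_along(seqs))))
  # every training sequence appears once per class, so no decision rule can
  # beat chance on a balanced probe drawn from the same generator
  probe_pos <- simulate_positives(30, seed = 32)
  probe_neg <- stats::setNames(simulate_positives(30, seed = 33),
                               paste0("n", 1:30))
  truth <- rep(c(1, 0), each = 30)
  pred <- predict(fit, c(probe_pos, probe_neg))$label == "STP"
  acc <- mean((truth == 1) == pred)
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
})

test_that("model artifacts round-trip as plain text with identical decisions", {
  fit <- stp_fit(simulate_positives(25, seed = 8),
                 simulate_negatives(30, seed = 8),
                 gamma = STP_TUNED_GAMMA, cost = 0.1)
  probe <- c(simulate_positives(50, seed = 9), simulate_negatives(50, seed = 9))
  f <- withr::local_tempfile(fileext = ".stpmodel")
  save_model(fit, f)

  # the artifact is text with key/value headers
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "# stpsvm-model format="))
  expect_true(any(grepl("meanP1=", lines[2:3])))

  back <- load_model(f)
  expect_identical(predict(back, probe), predict(fit, probe))
  expect_identical(back$feature_set, fit$feature_set)
  expect_equal(back$params, fit$params)
  expect_equal(back$gamma, STP_TUNED_GAMMA)

  # truncation is detected
  writeLines(lines[1:(length(lines) %/% 2)], f)
  expect_error(load_model(f), "corrupt")
  expect_error(load_model(file.path(tempdir(), "missing.stpmodel")),
               "no such file")
})

test_that("the subsampling protocol pools confusion counts and reproduces with a seed", {
  pos <- simulate_positives(40, seed = 13)
  neg <- simulate_negatives(60, seed = 13)
  ev1 <- stp_evaluate(pos, neg, n_pos_sample = 25, n_neg_sample = 40,
                      iterations = 15, seed = 99)
  ev2 <- stp_evaluate(pos, neg, n_pos_sample = 25, n_neg_sample = 40,
                      iterations = 15, seed = 99)
  expect_identical(ev1$pooled, ev2$pooled)
  expect_identical(ev1$iteration_metrics, ev2$iteration_metrics)
  expect_identical(ev1$auc, ev2$auc)

  # each iteration holds out the complement: 15 positives + 20 negatives
  expect_identical(sum(unclass(ev1$pooled)), 15L * 35L)
  expect_identical(nrow(ev1$iteration_metrics), 15L)
  # separable fixtures: near-perfect pooled metrics
  expect_gt(ev1$pooled_metrics[["accuracy"]], 0.95)
  expect_gt(ev1$auc, 0.98)

  expect_error(stp_evaluate(pos, neg, n_pos_sample = 100, n_neg_sample = 40,
                            iterations = 2), "more training samples")
})

test_that("stratified k-fold scores every chain exactly once", {
  pos <- simulate_positives(30, seed = 17)
  neg <- simulate_negatives(45, seed = 17)
  ev <- stp_evaluate(pos, neg, protocol = "kfold", k = 5, seed = 5)
  expect_identical(sum(unclass(ev$pooled)), 75L)
  expect_identical(ev$pooled[["TP"]] + ev$pooled[["FN"]], 30L)
  expect_gt(ev$pooled_metrics[["accuracy"]], 0.9)
  expect_error(stp_evaluate(pos, neg, protocol = "kfold", k = 40), "k must be")
})

test_that("held-out accuracy rises with class signal across generator regimes", {
  pos <- simulate_positives(60, seed = 23)
  hard <- simulate_negatives(90, seed = 23, hard = TRUE)
  easy <- simulate_negatives(90, seed = 23)
  # no-signal control: same sequences relabelled at random
  set.seed(23)
  all <- c(pos, easy)
  lab <- sample(rep(c(TRUE, FALSE), c(60, 90)))
  shuf_pos <- stats::setNames(all[lab], paste0("p", seq_len(sum(lab))))
  shuf_neg <- stats::setNames(all[!lab], paste0("n", seq_len(sum(!lab))))

  acc <- function(p, n) stp_evaluate(p, n, n_pos_sample = 40,
                                     n_neg_sample = 60, iterations = 20,
                                     seed = 7)$pooled_metrics[["accuracy"]]
  a_null <- acc(shuf_pos, shuf_neg)
  a_hard <- acc(pos, hard)
  a_easy <- acc(pos, easy)
  expect_lt(a_null, a_hard)
  expect_lte(a_hard, a_easy)
  expect_lt(abs(a_null - 0.5), 0.2)
})
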