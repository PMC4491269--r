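toy <- "GCAAAACAAAAACAACAAACAAAAAACGG"   # valid motif, loops 4,5,2,3,6
toy_params <- structure(c(meanP1 = 13, meanP2 = 12, meanP3 = 13),
                        class = "stp_norm")

test_that("proximity lengths span the sequentially pairing cysteines", {
  m <- scan_motif(toy)
  expect_equal(proximity_lengths(m), c(P1 = 13, P2 = 12, P3 = 13))
  expect_equal(proximity_lengths(scan_motif("CCCCCC")), c(P1 = 0, P2 = 0, P3 = 0))
  # arithmetic on adjacent window positions (white-box motif: the window
  # 1..6 is spanned by P_j = 2 enclosed cysteines each)
  adjacent <- structure(list(positions = 1:6, loops = rep(0L, 5),
                             min_loop_index = 1L, valid = TRUE,
                             reject_reason = "none", n_cys = 6L),
                        class = "stp_motif")
  expect_equal(proximity_lengths(adjacent), c(P1 = 2, P2 = 2, P3 = 2))
  # invariant: P_j exceeds the spanned loops by the two enclosed cysteines
  expect_equal(unname(proximity_lengths(m)),
               c(sum(m$loops[1:3]), sum(m$loops[2:4]), sum(m$loops[3:5])) + 2)
})

test_that("normalized proximity follows 100/(|P - mean| + 10)", {
  expect_identical(normalized_proximity(13, 13), 10)
  expect_identical(normalized_proximity(23, 13), 5)
  expect_identical(normalized_proximity(3, 13), 5)
  expect_equal(normalized_proximity(0, 13), 100 / 23)
  # strictly decreasing in the absolute deviation, bounded by (0, 10]
  devs <- 0:50
  np <- normalized_proximity(20 + devs, 20)
  expect_true(all(diff(np) < 0))
  expect_true(all(np > 0 & np <= 10))
  expect_equal(normalized_proximity(20 - (0:20), 20), np[1:21])
})

test_that("least loop ratio and inter-loop presence read the anchored window", {
  m <- scan_motif(toy)
  expect_equal(least_loop_ratio(m, nchar(toy)), 2 / 29)
  expect_equal(least_loop_ratio(anchor_motif(positions_from_loops(
    c(5L, 4L, 3L, 6L, 7L), nflank = 0L)), 30), 0.1)
  invalid <- scan_motif("MKV")
  expect_identical(least_loop_ratio(invalid, 3), 0)

  expect_identical(interloop_presence(m), 1L)
  expect_identical(interloop_presence(invalid), 0L)
  # adjacent C4-C5 zeroes the flag even for a valid motif
  m2 <- anchor_motif(positions_from_loops(c(4L, 5L, 1L, 0L, 6L)))
  expect_true(m2$valid)
  expect_identical(interloop_presence(m2), 0L)
})

test_that("residue frequencies are fractions over the whole chain", {
  expect_equal(residue_frequencies("CCSS"),
               c(C = 0.5, S = 0.5, H = 0, K = 0, L = 0))
  expect_equal(residue_frequencies("AAAA", "C"), c(C = 0))
  expect_equal(residue_frequencies(toy, "C"), c(C = 6 / 29))
})

test_that("normalization constants average the valid positives only", {
  p10 <- seq_from_loops(c(3L, 3L, 2L, 3L, 5L))   # P1 = 3+3+2+2 = 10
  p14 <- seq_from_loops(c(5L, 5L, 2L, 3L, 5L))   # P1 = 5+5+2+2 = 14
  fit <- fit_normalization(c(a = p10, b = p14))
  expect_equal(fit[["meanP1"]], 12)
  one <- fit_normalization(c(a = p10))
  expect_equal(unname(unclass(one)),
               unname(proximity_lengths(scan_motif(p10))))
  # invalid positives are excluded from the mean
  withnoise <- c(a = p10, b = p14, junk = "MKVLL")
  expect_equal(fit_normalization(withnoise)[["meanP1"]], 12)
  expect_error(fit_normalization(c(x = "MKVLL")), "no positive sequence")
})

test_that("featurize assembles the configured feature sets deterministically", {
  X <- featurize(c(toy = toy), toy_params, 6L)
  expect_identical(colnames(X),
                   c("NP1", "NP2", "NP3", "least_loop_ratio", "interloop_flag",
                     "freq_C", "freq_S", "freq_H", "freq_K", "freq_L"))
  expect_equal(unname(X[1, ]),
               c(10, 10, 10, 2 / 29, 1, 6 / 29, 0, 0, 0, 0))

  # chains without cysteines flow through the zero-P rule
  X0 <- featurize(c(none = "MKVLNNNAA"), toy_params, 6L)
  expect_equal(unname(X0[1, 1:3]), 100 / (unclass(toy_params) + 10),
               ignore_attr = TRUE)
  expect_equal(unname(X0[1, 4:6]), c(0, 0, 0))

  # determinism
  expect_identical(featurize(c(toy = toy), toy_params, 6L), X)

  # layouts of the non-canonical nested sets
  expect_identical(colnames(featurize(c(t = toy), toy_params, 1L)),
                   paste0("freq_", c("C", "S", "H", "K", "L")))
  expect_identical(colnames(featurize(c(t = toy), toy_params, 2L)),
                   c("NP1", "NP2", "NP3"))
  expect_identical(colnames(featurize(c(t = toy), toy_params, 4L)),
                   c("NP1", "NP2", "NP3", "least_loop_ratio", "interloop_flag"))
  expect_error(featurize(c(t = toy), toy_params, 9L), "unknown feature set")
})

test_that("features ignore non-alphabet residue identity outside frequencies", {
  set.seed(19)
  for (i in 1:50) {
    s <- random_peptide(sample(30:90, 1), 6)
    chars <- strsplit(s, "")[[1]]
    swap <- which(!chars %in% c("C", "S", "H", "K", "L"))
    chars[swap] <- sample(c("G", "W", "V"), length(swap), replace = TRUE)
    s2 <- paste(chars, collapse = "")
    params <- structure(c(meanP1 = 14, meanP2 = 14, meanP3 = 14),
                        class = "stp_norm")
    X1 <- featurize(c(x = s), params, 4L)
    X2 <- featurize(c(x = s2), params, 4L)
    expect_identical(X1, X2)
  }
})
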