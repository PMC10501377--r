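test_that("the printed C2F4 pair is linked into one series with spacing 2", {
  feats <- data.frame(feature_id = c("a", "b"), mz = c(475.9310, 575.9227))
  ser <- detect_series(feats)
  expect_length(ser, 1)
  expect_equal(ser[[1]]$members, c("a", "b"))
  expect_equal(ser[[1]]$unit_counts, 2L)
  expect_true(validate_series(ser[[1]]))
})

test_that("single features and sparse inputs yield no series", {
  expect_length(detect_series(data.frame(feature_id = "a", mz = 475.9310)), 0)
  expect_error(detect_series(data.frame(feature_id = "a", mz = 1),
                             min_members = 1), "at least 2")
})

test_that("planted homologues are recovered exactly from a noisy background", {
  set.seed(71)
  # 5 PFSA homologues (C4-C8) on 50 hydrogen-rich matrix features
  pfsa_mz <- vapply(4:8, function(n)
    ion_mz(sprintf("C%dHF%dSO3", n, 2 * n + 1), "deprotonated"), numeric(1))
  matrix_mz <- replicate(50, {
    c_n <- sample(14:40, 1)
    h_n <- round(c_n * runif(1, 1.3, 2.1))
    ion_mz(sprintf("C%dH%dO%d", c_n, h_n, sample(1:8, 1)), "deprotonated")
  })
  feats <- data.frame(
    feature_id = sprintf("f%02d", 1:55),
    mz = c(pfsa_mz, matrix_mz))
  ser <- detect_series(feats, min_members = 3)
  expect_length(ser, 1)
  expect_setequal(ser[[1]]$members, sprintf("f%02d", 1:5))
  expect_equal(ser[[1]]$unit_counts, rep(1L, 4))

  # brute-force all-pairs oracle: transitive closure over eligible pairs
  kv <- kendrick(feats$mz)
  n <- nrow(feats)
  eligible <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- abs(feats$mz[j] - feats$mz[i])
    k <- round(d / cf2_mass())
    if (k >= 1 && abs(d - k * cf2_mass()) <= 0.01 * k &&
        abs(kv$kmd[i] - kv$kmd[j]) <= 0.01)
      eligible[i, j] <- eligible[j, i] <- TRUE
  }
  comp <- seq_len(n)
  repeat {
    new <- vapply(seq_len(n), function(i)
      min(comp[c(i, which(eligible[i, ]))]), numeric(1))
    if (identical(new, comp)) break
    comp <- new
  }
  big <- names(table(comp))[table(comp) >= 3]
  oracle_groups <- lapply(big, function(g) feats$feature_id[comp == as.numeric(g)])
  expect_length(oracle_groups, 1)
  expect_setequal(oracle_groups[[1]], ser[[1]]$members)
})

test_that("series detection is permutation invariant and locally stable", {
  feats <- data.frame(
    feature_id = c("a", "b", "c", "far"),
    mz = c(475.9310, 525.9278, 575.9227, 801.2345))
  ser1 <- detect_series(feats)
  ser2 <- detect_series(feats[c(3, 1, 4, 2), ])
  expect_equal(length(ser1), length(ser2))
  expect_equal(ser1[[1]]$members, ser2[[1]]$members)
  # the far feature does not perturb the series
  ser3 <- detect_series(feats[1:3, ])
  expect_equal(ser1[[1]]$members, ser3[[1]]$members)
  expect_setequal(ser1[[1]]$members, c("a", "b", "c"))
})

test_that("reported series always satisfy their own invariants", {
  set.seed(81)
  for (rep in 1:5) {
    mz <- sort(runif(30, 150, 900))
    feats <- data.frame(feature_id = sprintf("x%02d", 1:30), mz = mz)
    for (s in detect_series(feats))
      expect_true(validate_series(s))
  }
})

test_that("RT consistency requires elution order to follow homologue mass", {
  ser <- structure(list(members = c("a", "b", "c"),
                        mz = c(399, 449, 499), rt = c(5.0, 5.8, 6.7),
                        unit_counts = c(1L, 1L), unit = "CF2",
                        unit_mass = cf2_mass(), kmd = rep(0, 3),
                        mean_kmd = 0), class = "homologue_series")
  expect_true(series_rt_consistency(ser))

  ser$rt <- c(6.0, 5.0, 6.7)
  expect_false(series_rt_consistency(ser))

  ser$rt <- c(5.0, 5.0, 5.0)
  expect_false(series_rt_consistency(ser, slack = 0))
  expect_true(series_rt_consistency(ser, slack = 0.1))

  ser$rt <- c(5.0, NA, 6.0)
  expect_error(series_rt_consistency(ser), "retention")
})

test_that("KMD plot export labels series members", {
  feats <- data.frame(feature_id = c("a", "b", "c"),
                      mz = c(475.9310, 575.9227, 300.2000))
  ser <- detect_series(feats)
  tab <- kmd_plot_table(feats, ser)
  expect_equal(tab$series_id, c("S01", "S01", NA))
  expect_equal(tab$kmd, kendrick(feats$mz)$kmd)
})
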