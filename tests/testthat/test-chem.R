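test_that("formula parsing handles compositions, charges and round-trips", {
  f <- parse_formula("C9H5F13NO4S")
  expect_equal(unclass(f$counts)[c("C", "H", "F", "N", "O", "S")],
               c(C = 9L, H = 5L, F = 13L, N = 1L, O = 4L, S = 1L))
  expect_equal(f$charge, 0L)
  expect_equal(parse_formula("C9H5F13NO4S-")$charge, -1L)
  expect_equal(unclass(parse_formula("H")$counts), c(H = 1L))
  g <- parse_formula("C6HF13SO4")
  expect_equal(unclass(g$counts)[c("C", "H", "F", "S", "O")],
               c(C = 6L, H = 1L, F = 13L, S = 1L, O = 4L))

  expect_error(parse_formula("C2Xx4"), "Xx")
  expect_error(parse_formula(""), "non-empty")
  expect_error(parse_formula("-"), "composition")

  # formatting emits Hill order (C, H, then alphabetical)
  for (s in c("C9H5F13NO4S-", "H2O", "CH4", "C8HClF16O3S"))
    expect_identical(format_formula(parse_formula(s)), s)
  # parse-format-parse is the identity for any element order
  for (s in c("C6HF13SO4", "SO3-", "NO2S-", "C6F13SO2NH")) {
    f <- parse_formula(s)
    expect_equal(parse_formula(format_formula(f)), f)
  }
})

test_that("monoisotopic masses match hand sums and are additive", {
  expect_equal(monoisotopic_mass("CF2"), 49.996806, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C"), 12, tolerance = 1e-12)
  expect_equal(round(monoisotopic_mass("C3H4O2"), 4), 72.0211)

  # additivity: mass(f1 (+) f2) = mass(f1) + mass(f2)
  set.seed(7)
  els <- element_table()$element
  for (i in 1:20) {
    n1 <- setNames(sample(0:4, 4, replace = TRUE), sample(els, 4))
    n2 <- setNames(sample(0:4, 4, replace = TRUE), sample(els, 4))
    if (sum(n1) == 0 || sum(n2) == 0) next
    joint <- tapply(c(n1, n2), names(c(n1, n2)), sum)
    joint <- setNames(as.integer(joint), names(joint))
    expect_equal(monoisotopic_mass(new_formula(joint)),
                 monoisotopic_mass(new_formula(n1[n1 > 0])) +
                   monoisotopic_mass(new_formula(n2[n2 > 0])),
                 tolerance = 1e-9)
  }
})

test_that("ion m/z includes the electron mass in both conventions", {
  expect_equal(round(ion_mz("C9H5F13NO4S-", "ion"), 4), 469.9737)
  expect_equal(round(ion_mz("C6HF13SO4", "deprotonated"), 4), 414.9315)
  expect_equal(round(ion_mz("H2O", "deprotonated"), 4), 17.0033)
  expect_error(ion_mz("CF4", "deprotonated"), "no hydrogen")

  # deprotonation identity: [M-H]- = M - 1.007825 + 0.000549
  set.seed(11)
  for (i in 1:20) {
    f <- new_formula(c(C = sample(1:20, 1), H = sample(1:30, 1),
                       O = sample(0:5, 1), F = sample(0:10, 1)))
    expect_equal(ion_mz(f, "deprotonated"),
                 monoisotopic_mass(f) - 1.007825 + 0.000549,
                 tolerance = 1e-6)
  }
})

test_that("ppm error is signed and scaled correctly", {
  expect_equal(ppm_error(469.9736, 469.9737), -0.21, tolerance = 0.05)
  expect_equal(ppm_error(500, 500), 0)
  expect_equal(ppm_error(500.0050, 500.0000), 10.0, tolerance = 1e-6)
  expect_error(ppm_error(500, 0), "positive")
})

test_that("ring-and-double-bond equivalents follow the standard formula", {
  expect_equal(as.numeric(rdb("C9H6F13NO4S")), 1.0)
  expect_equal(as.numeric(rdb("CH4")), 0.0)
  expect_equal(as.numeric(rdb("C6H6")), 4.0)
  ionic <- rdb("C9H5F13NO4S")  # ion composition -> half-integral
  expect_equal(as.numeric(ionic), 1.5)
  expect_true(attr(ionic, "ionic"))
  expect_false(attr(rdb("C6H6"), "ionic"))
})

test_that("first-isotope ratio matches a brute-force convolution oracle", {
  expect_equal(isotope_m1_ratio("C"), 0.010816, tolerance = 1e-4)
  expect_equal(isotope_m1_ratio("F13"), 0)

  # oracle: convolve per-atom isotope distributions over nominal mass
  # offsets and take the (M+1)/M coefficient ratio
  oracle <- function(f) {
    tab <- element_table()
    dist <- c(1)  # probability by nominal offset, starting at +0
    for (el in names(f$counts)) {
      r <- tab$m1_ratio[tab$element == el]
      p1 <- r / (1 + r); p0 <- 1 - p1
      atom <- c(p0, p1)
      for (k in seq_len(f$counts[[el]])) {
        new <- numeric(length(dist) + 1)
        new[seq_along(dist)] <- dist * atom[1]
        new[seq_along(dist) + 1] <- new[seq_along(dist) + 1] + dist * atom[2]
        dist <- new
      }
    }
    dist[2] / dist[1]
  }
  set.seed(3)
  for (i in 1:25) {
    counts <- c(C = sample(0:12, 1), H = sample(0:12, 1), N = sample(0:3, 1),
                O = sample(0:4, 1), S = sample(0:2, 1))
    if (sum(counts) == 0 || sum(counts) > 30) next
    f <- new_formula(counts[counts > 0])
    expect_equal(isotope_m1_ratio(f), oracle(f), tolerance = 1e-6)
  }
})

test_that("Kendrick mass defect reproduces hand-computed values", {
  expect_lt(abs(kendrick(469.9736)$kmd - (-0.0036)), 5e-4)
  expect_lt(abs(kendrick(575.9227)$kmd - 0.0405), 5e-4)
  expect_equal(kendrick(cf2_mass())$kendrick_mass, 50, tolerance = 1e-9)
  expect_equal(kendrick(cf2_mass())$kmd, 0, tolerance = 1e-9)
  expect_error(kendrick(-1), "positive")
  expect_error(kendrick(0), "positive")
})

test_that("KMD is invariant under CF2 shifts", {
  set.seed(5)
  m <- runif(50, 80, 900)
  for (k in 1:10)
    expect_equal(kendrick(m + k * cf2_mass())$kmd, kendrick(m)$kmd,
                 tolerance = 1e-9)
})
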