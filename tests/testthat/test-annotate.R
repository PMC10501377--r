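lib_spec <- function() ms2_spectrum(498.9302,
                                    mz = c(79.9574, 98.9556),
                                    intensity = c(100, 50))

test_that("fit score measures intensity-weighted library coverage", {
  lib <- lib_spec()
  full <- ms2_spectrum(498.9302, mz = c(79.9574, 98.9556, 150.0),
                       intensity = c(80, 40, 10))
  expect_equal(fit_score(full, lib), 100)
  expect_equal(fit_score(lib, lib), 100)

  partial <- ms2_spectrum(498.9302, mz = 79.9574, intensity = 100)
  expect_equal(fit_score(partial, lib), 66.7, tolerance = 0.05)

  # monotone non-decreasing as query peaks are added
  s1 <- fit_score(partial, lib)
  grown <- ms2_spectrum(498.9302, mz = c(79.9574, 98.9556), intensity = c(1, 1))
  expect_gte(fit_score(grown, lib), s1)
  expect_error(ms2_spectrum(100, numeric(0), numeric(0)), "at least one")
})

test_that("library search enforces all four hit criteria conjunctively", {
  lib_entry <- list(name = "PFOS", formula = "C8HF17SO3",
                    ion_mode = "deprotonated", spectrum = lib_spec())
  theo <- ion_mz("C8HF17SO3", "deprotonated")
  reps <- replicate(3, lib_spec(), simplify = FALSE)

  hits <- library_search(theo, reps, list(lib_entry))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$name, "PFOS")
  expect_equal(hits$replicate_count, 3)

  # score below 80: a query missing the dominant library peak scores 33.3
  weak <- replicate(3, ms2_spectrum(theo, 98.9556, 100), simplify = FALSE)
  expect_equal(nrow(library_search(theo, weak, list(lib_entry))), 0)

  # mass error 6 ppm fails despite a perfect spectrum
  expect_equal(nrow(library_search(theo * (1 + 6e-6), reps, list(lib_entry))), 0)

  # only 2 replicate spectra fails the triplicate criterion
  expect_equal(nrow(library_search(theo, reps[1:2], list(lib_entry))), 0)

  # RT inconsistency fails
  expect_equal(nrow(library_search(theo, reps, list(lib_entry),
                                   rt_consistent = FALSE)), 0)

  # no MS/MS -> empty result, not an error
  expect_equal(nrow(library_search(theo, list(), list(lib_entry))), 0)
})

test_that("suspect screening applies ppm and optional isotope criteria", {
  suspects <- data.frame(name = "O-PFHpS/PFHx-OS", formula = "C6HF13SO4",
                         ion_mode = "deprotonated", stringsAsFactors = FALSE)
  hits <- suspect_screen(414.9315, suspects)
  expect_equal(nrow(hits), 1)
  expect_lt(abs(hits$ppm), 0.2)
  expect_true(is.na(hits$isotope_diff_pct))

  expect_equal(nrow(suspect_screen(414.9515, suspects)), 0)  # ~48 ppm off

  # observed 10 % vs theoretical 9.7 % is a 3.1 % difference: pass
  hits <- suspect_screen(414.9315, suspects,
                         observed_m1_ratio = 1.031 * isotope_m1_ratio("C6HF13SO4"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$isotope_diff_pct, 3.1, tolerance = 0.01)
  # 6 % difference fails
  expect_equal(nrow(suspect_screen(414.9315, suspects,
    observed_m1_ratio = 1.06 * isotope_m1_ratio("C6HF13SO4"))), 0)

  # hit set shrinks monotonically as the ppm tolerance tightens
  many <- data.frame(name = sprintf("s%d", 1:40),
                     formula = sprintf("C%dH%dO2", 5:44, 7:46),
                     ion_mode = "deprotonated", stringsAsFactors = FALSE)
  mz0 <- ion_mz("C20H22O2", "deprotonated")
  prev <- Inf
  for (tol in c(50, 20, 5, 1)) {
    n <- nrow(suspect_screen(mz0 * (1 + 3e-6), many, max_ppm = tol))
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("neutral losses annotate propionate and SO2 mass differences", {
  spec <- ms2_spectrum(469.9736, mz = c(77.9655, 397.9527),
                       intensity = c(60, 100))
  nl <- neutral_losses(spec)
  c3 <- nl[nl$loss_formula == "C3H4O2", ]
  expect_equal(nrow(c3), 1)
  expect_equal(c3$from_mz, 469.9736)
  expect_equal(c3$to_mz, 397.9527)
  expect_equal(c3$loss_mass, 72.0209, tolerance = 1e-4)

  spec2 <- ms2_spectrum(575.9227, mz = c(92.9888, 156.9513),
                        intensity = c(100, 55))
  nl2 <- neutral_losses(spec2)
  so2 <- nl2[nl2$loss_formula == "SO2", ]
  expect_equal(nrow(so2), 1)
  expect_equal(so2$loss_mass, 63.9625, tolerance = 1e-4)
  expect_equal(so2$from_mz, 156.9513)

  lonely <- ms2_spectrum(400.123, mz = 123.456, intensity = 1)
  expect_equal(nrow(neutral_losses(lonely)), 0)
})

test_that("fragment rules reproduce the diagnostic class calls", {
  # sulfonate class: SO3- and FSO3- present
  pfsa <- ms2_spectrum(498.9302, mz = c(79.9574, 98.9558),
                       intensity = c(100, 45))
  cls <- classify_by_fragments(pfsa)
  expect_true(cls$satisfied[cls$class_label == "PFSA"])

  # sulfonamido-propanoate: NO2S- fragment plus C3H4O2 neutral loss
  prA <- ms2_spectrum(469.9737, mz = c(77.9655, 469.9737 - 72.0211),
                      intensity = c(60, 100))
  cls <- classify_by_fragments(prA)
  expect_true(cls$satisfied[cls$class_label == "FASA-PrA"])

  # N-methyl sulfonamide class: CH3NO2S-/CH3NO4S2- present, SO3- absent
  mefasa <- ms2_spectrum(475.9301,
                         mz = c(77.9655, 92.9890, 156.9509),
                         intensity = c(40, 100, 55))
  cls <- classify_by_fragments(mefasa)
  expect_true(cls$satisfied[cls$class_label == "MeFASA-SO2"])

  # adding the forbidden sulfonate fragment vetoes the class
  with_so3 <- ms2_spectrum(475.9301,
                           mz = c(77.9655, 79.9574, 92.9890, 156.9509),
                           intensity = c(40, 90, 100, 55))
  cls <- classify_by_fragments(with_so3)
  expect_false(cls$satisfied[cls$class_label == "MeFASA-SO2"])

  # a bare uninformative spectrum satisfies nothing
  none <- classify_by_fragments(ms2_spectrum(400, 200.123, 1))
  expect_false(any(none$satisfied))
  expect_error(classify_by_fragments(pfsa, rules = list()), "non-empty")
})

test_that("the confidence ladder reproduces the documented assignments", {
  lib_hit <- data.frame(name = "PFOS", theoretical_mz = 498.9302, ppm = 0.1,
                        best_score = 100, replicate_count = 3L,
                        rt_consistent = TRUE, stringsAsFactors = FALSE)
  sus_hit <- data.frame(name = "x", formula = "C6HF13SO4",
                        class_label = NA, theoretical_mz = 414.9315,
                        ppm = 0.1, isotope_diff_pct = NA,
                        stringsAsFactors = FALSE)
  diag_ev <- data.frame(class_label = "FASA", matched = "frag:NO2S",
                        n_matched = 1L, forbidden_present = FALSE,
                        satisfied = TRUE, stringsAsFactors = FALSE)

  lvl <- function(e) as.character(assign_confidence(e)$confidence)

  # standard-confirmed library hit
  expect_equal(lvl(annotation_evidence("f", library_hits = lib_hit,
                                       has_reference_standard_match = TRUE)),
               "1a")
  # library MS/MS match without a standard in hand
  expect_equal(lvl(annotation_evidence("f", library_hits = lib_hit)), "1b")
  # diagnostic fragments, unique known structure, no standard
  expect_equal(lvl(annotation_evidence("f", class_evidence = diag_ev)), "2a")
  # diagnostic fragments with positional isomer candidates
  expect_equal(lvl(annotation_evidence("f", class_evidence = diag_ev,
                                       isomer_ambiguity = TRUE)), "3a")
  # novel structure proposed from fragmentation alone
  expect_equal(lvl(annotation_evidence("f", class_evidence = diag_ev,
                                       structure_known = FALSE)), "3b")
  # unequivocal formula, nothing structural
  expect_equal(lvl(annotation_evidence("f", formula_unequivocal = TRUE)), "4")
  # suspect exact-mass match only
  expect_equal(lvl(annotation_evidence("f", suspect_hits = sus_hit)), "5a")
  # indistinguishable isomer pair with poor MS/MS
  expect_equal(lvl(annotation_evidence("f", suspect_hits = sus_hit,
                                       isomer_ambiguity = TRUE)), "5b")
  # nothing at all
  expect_equal(lvl(annotation_evidence("f")), "5b")
})

test_that("downgrading evidence never raises the confidence level", {
  order_levels <- c("1a", "1b", "2a", "2b", "3a", "3b", "4", "5a", "5b")
  rank <- function(l) match(l, order_levels)
  lib_hit <- data.frame(name = "PFOS", theoretical_mz = 498.9302, ppm = 0.1,
                        best_score = 100, replicate_count = 3L,
                        rt_consistent = TRUE, stringsAsFactors = FALSE)
  diag_ev <- data.frame(class_label = "FASA", matched = "frag:NO2S",
                        n_matched = 1L, forbidden_present = FALSE,
                        satisfied = TRUE, stringsAsFactors = FALSE)
  full <- annotation_evidence("f", library_hits = lib_hit,
                              class_evidence = diag_ev,
                              has_reference_standard_match = TRUE)
  lvl_full <- assign_confidence(full)$confidence

  drops <- list(
    annotation_evidence("f", library_hits = lib_hit, class_evidence = diag_ev),
    annotation_evidence("f", class_evidence = diag_ev),
    annotation_evidence("f"))
  prev <- rank(as.character(lvl_full))
  for (d in drops) {
    r <- rank(as.character(assign_confidence(d)$confidence))
    expect_gte(r, prev)
    prev <- r
  }
})
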