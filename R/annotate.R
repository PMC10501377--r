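#' Construct an MS/MS spectrum
#'
#' @param precursor_mz Precursor m/z (Da).
#' @param mz,intensity Fragment peak vectors (equal length, at least one
#'   peak, intensities >= 0). Peaks are stored sorted by m/z.
#' @param acquisition `"dda"` or `"swath"`.
#' @param collision_energy Optional collision energy (eV).
#' @return An object of class `ms2_spectrum`.
#' @export
ms2_spectrum <- function(precursor_mz, mz, intensity,
                         acquisition = c("dda", "swath"),
                         collision_energy = NA_real_) {
  acquisition <- match.arg(acquisition)
  if (length(mz) != length(intensity) || length(mz) == 0)
    stop("spectrum needs at least one (mz, intensity) peak pair")
  if (any(intensity < 0)) stop("peak intensities must be non-negative")
  o <- order(mz)
  structure(list(precursor_mz = precursor_mz, mz = mz[o],
                 intensity = intensity[o], acquisition = acquisition,
                 collision_energy = collision_energy),
            class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf("<ms2_spectrum> precursor %.4f | %d peaks | %s\n",
              x$precursor_mz, length(x$mz), x$acquisition))
  invisible(x)
}

#' Library "fit" score
#'
#' Measures how completely a library spectrum is contained in a query
#' spectrum: the intensity-weighted fraction of library peaks that have a
#' query peak within `frag_tol`, scaled to 0-100. A score of 100 means all
#' library peaks (by intensity) are present in the unknown spectrum.
#'
#' @param query,library `ms2_spectrum` objects.
#' @param frag_tol Fragment matching tolerance (Da, default 0.01).
#' @return Score in \[0, 100\].
#' @export
fit_score <- function(query, library, frag_tol = 0.01) {
  stopifnot(inherits(query, "ms2_spectrum"), inherits(library, "ms2_spectrum"))
  matched <- vapply(library$mz, function(m) any(abs(query$mz - m) <= frag_tol),
                    logical(1))
  100 * sum(library$intensity[matched]) / sum(library$intensity)
}

#' Spectral-library search for one feature
#'
#' A library entry is accepted as a true hit when all four criteria hold:
#' precursor mass error below `max_ppm`, fit score at least `min_score`,
#' the match succeeds in at least `min_replicates` replicate spectra of the
#' feature, and the feature's retention time is consistent with its
#' homologue series (caller-supplied flag).
#'
#' @param feature_mz Consensus feature m/z.
#' @param spectra List of replicate `ms2_spectrum` objects for the feature
#'   (may be empty: returns no hits).
#' @param library List of entries, each a list with `name`, `formula` (ion
#'   formula string or `formula_counts`), `ion_mode` (`"ion"` or
#'   `"deprotonated"`) and `spectrum` (`ms2_spectrum`).
#' @param rt_consistent Logical: RT consistent with homologue mass trend.
#' @param max_ppm Mass-error criterion (strict `<`, default 5).
#' @param min_score Fit-score criterion (inclusive `>=`, default 80).
#' @param min_replicates Replicate-spectra criterion (default 3).
#' @param frag_tol Fragment tolerance for [fit_score()].
#' @return Data frame of hits (name, theoretical_mz, ppm, best_score,
#'   replicate_count, rt_consistent), sorted by decreasing score.
#' @export
library_search <- function(feature_mz, spectra, library, rt_consistent = TRUE,
                           max_ppm = 5, min_score = 80, min_replicates = 3,
                           frag_tol = 0.01) {
  hits <- lapply(library, function(entry) {
    theo <- ion_mz(entry$formula, mode = entry$ion_mode %||% "ion")
    ppm <- ppm_error(feature_mz, theo)
    if (abs(ppm) >= max_ppm) return(NULL)
    if (length(spectra) == 0) return(NULL)
    scores <- vapply(spectra, fit_score, numeric(1),
                     library = entry$spectrum, frag_tol = frag_tol)
    nrep <- sum(scores >= min_score)
    if (nrep < min_replicates || !isTRUE(rt_consistent)) return(NULL)
    data.frame(name = entry$name, theoretical_mz = theo, ppm = ppm,
               best_score = max(scores), replicate_count = nrep,
               rt_consistent = TRUE, stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) return(.empty_hits_df())
  hits[order(-hits$best_score), , drop = FALSE]
}

.empty_hits_df <- function() {
  data.frame(name = character(0), theoretical_mz = numeric(0),
             ppm = numeric(0), best_score = numeric(0),
             replicate_count = integer(0), rt_consistent = logical(0),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Suspect screening by exact mass and isotope ratio
#'
#' A suspect matches when its theoretical ion m/z lies within `max_ppm`
#' (strict) of the observed feature m/z, and -- when an observed M+1/M
#' ratio is available -- the percent difference between observed and
#' predicted first-isotope ratios is below `max_iso_diff`. Features without
#' an observed isotope ratio skip (not fail) the isotope criterion.
#'
#' @param feature_mz Observed consensus m/z.
#' @param suspects Data frame with columns `name`, `formula`, `ion_mode`
#'   (`"ion"` or `"deprotonated"`), and optionally `class_label`, `source`.
#' @param observed_m1_ratio Observed (M+1)/M intensity ratio, or NA.
#' @param max_ppm Mass-error criterion (strict `<`, default 5 ppm).
#' @param max_iso_diff Isotope-ratio percent-difference criterion (strict
#'   `<`, default 5).
#' @return Data frame of hits: name, formula, class_label, theoretical_mz,
#'   ppm, isotope_diff_pct (NA when skipped).
#' @export
suspect_screen <- function(feature_mz, suspects, observed_m1_ratio = NA_real_,
                           max_ppm = 5, max_iso_diff = 5) {
  rows <- lapply(seq_len(nrow(suspects)), function(i) {
    theo <- ion_mz(suspects$formula[i], mode = suspects$ion_mode[i])
    ppm <- ppm_error(feature_mz, theo)
    if (abs(ppm) >= max_ppm) return(NULL)
    iso_diff <- NA_real_
    if (!is.na(observed_m1_ratio)) {
      theo_r <- isotope_m1_ratio(suspects$formula[i])
      if (theo_r > 0) {
        iso_diff <- abs(observed_m1_ratio - theo_r) / theo_r * 100
        if (iso_diff >= max_iso_diff) return(NULL)
      }
    }
    data.frame(name = suspects$name[i], formula = suspects$formula[i],
               class_label = if ("class_label" %in% names(suspects))
                 suspects$class_label[i] else NA_character_,
               theoretical_mz = theo, ppm = ppm, isotope_diff_pct = iso_diff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(0), formula = character(0),
                      class_label = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0), isotope_diff_pct = numeric(0),
                      stringsAsFactors = FALSE)
  out[order(abs(out$ppm)), , drop = FALSE]
}

#' Built-in neutral-loss table
#'
#' Exact masses of the neutral losses diagnostic for PFAS fragmentation:
#' CF2 and C2F4 homologue units, SO2, the propionate-group loss C3H4O2,
#' HF, CO2, and the perfluoroalkyl radicals C6F13 and C8F17.
#'
#' @return Data frame with columns `formula` and `mass`.
#' @export
neutral_loss_table <- function() {
  losses <- c("CF2", "C2F4", "SO2", "C3H4O2", "HF", "CO2", "C6F13", "C8F17")
  data.frame(formula = losses,
             mass = vapply(losses, monoisotopic_mass, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Annotate neutral losses in a spectrum
#'
#' Computes precursor-to-fragment and fragment-to-fragment mass
#' differences and annotates each with the matching entries of a neutral
#' loss table within `tol`.
#'
#' @param spec An `ms2_spectrum` with a precursor m/z.
#' @param losses Loss table (default [neutral_loss_table()]).
#' @param tol Matching tolerance (Da, default 0.005).
#' @return Data frame of annotated differences: `from_mz`, `to_mz`,
#'   `loss_mass` (observed), `loss_formula`, `loss_theoretical`, `delta`.
#'   Empty when no difference matches the table.
#' @export
neutral_losses <- function(spec, losses = neutral_loss_table(), tol = 0.005) {
  stopifnot(inherits(spec, "ms2_spectrum"))
  pairs_from <- numeric(0); pairs_to <- numeric(0)
  for (m in spec$mz) { pairs_from <- c(pairs_from, spec$precursor_mz); pairs_to <- c(pairs_to, m) }
  n <- length(spec$mz)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pairs_from <- c(pairs_from, spec$mz[j]); pairs_to <- c(pairs_to, spec$mz[i])
    }
  }
  d <- pairs_from - pairs_to
  out <- lapply(seq_along(d), function(k) {
    hit <- which(abs(losses$mass - d[k]) <= tol)
    if (!length(hit)) return(NULL)
    data.frame(from_mz = pairs_from[k], to_mz = pairs_to[k],
               loss_mass = d[k], loss_formula = losses$formula[hit],
               loss_theoretical = losses$mass[hit],
               delta = d[k] - losses$mass[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(from_mz = numeric(0), to_mz = numeric(0),
                      loss_mass = numeric(0), loss_formula = character(0),
                      loss_theoretical = numeric(0), delta = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Built-in diagnostic fragment rules for PFAS classes
#'
#' Encodes the class-diagnostic fragmentation logic used in negative-mode
#' PFAS screening: sulfonic acids (PFSA, Cl-PFSA) show the sulfonate
#' fragment SO3- (79.9574) and FSO3-; carboxylic acids (PFCA) lose CO2;
#' perfluoroalkane sulfonamides (FASA) show NO2S- (77.9655); the
#' sulfonamido-propanoate class (FASA-PrA) adds the C3H4O2 propionate-group
#' neutral loss; and the N-methyl sulfonamide class shows CH3NO2S-
#' (theoretical 92.9890; printed observed value 92.9888) together with
#' perfluoroalkyl-chain losses while the sulfonate fragment SO3- is
#' *absent*. (Published tables sometimes label m/z 77.9655 "SO3-"; that
#' mass matches the NO2S- composition, and SO3- proper is 79.9574. Likewise
#' a fragment printed at 397.9527 with label C6F13SO3NH better matches the
#' C6F13SO2NH- composition, and 423.9629 deviates ~12 ppm from
#' C8H3F13NO2S-; both are carried here at their compositional masses.)
#'
#' @return A list of `fragment_rule` objects, each a list with
#'   `class_label`, `fragments` (data frame: formula, mz, role in
#'   required/forbidden), `losses` (character vector of loss formulas) and
#'   `min_matches`.
#' @export
fragment_rules <- function() {
  frag <- function(formulas, role = "required") {
    data.frame(formula = formulas,
               mz = vapply(formulas, function(f) ion_mz(paste0(f, "-"), "ion"),
                           numeric(1)),
               role = rep(role, length(formulas)), stringsAsFactors = FALSE)
  }
  rule <- function(class_label, fragments, losses = character(0),
                   min_matches = 1L) {
    structure(list(class_label = class_label, fragments = fragments,
                   losses = losses, min_matches = as.integer(min_matches)),
              class = "fragment_rule")
  }
  list(
    rule("PFSA", frag(c("SO3", "FSO3")), min_matches = 1L),
    rule("PFCA", frag(character(0)), losses = "CO2", min_matches = 1L),
    rule("FASA", frag("NO2S"), min_matches = 1L),
    rule("FASA-PrA", frag(c("NO2S", "C6F13SO2NH")), losses = "C3H4O2",
         min_matches = 2L),
    rule("MeFASA-SO2",
         rbind(frag(c("CH3NO2S", "CH3NO4S2")), frag("SO3", role = "forbidden")),
         losses = c("C6F13", "C8F17"), min_matches = 2L)
  )
}

#' Classify a spectrum by diagnostic fragments and neutral losses
#'
#' For each rule, records which required fragments and neutral losses are
#' present within `frag_tol`; a rule is satisfied when at least
#' `min_matches` requirements are met and no forbidden fragment is present.
#'
#' @param spec An `ms2_spectrum`.
#' @param rules List of fragment rules (default [fragment_rules()]).
#' @param frag_tol Fragment matching tolerance (Da, default 0.01).
#' @param loss_tol Neutral-loss matching tolerance (Da, default 0.005).
#' @return Data frame: `class_label`, `matched` (semicolon-joined matched
#'   requirements), `n_matched`, `forbidden_present`, `satisfied`.
#' @export
classify_by_fragments <- function(spec, rules = fragment_rules(),
                                  frag_tol = 0.01, loss_tol = 0.005) {
  if (!length(rules)) stop("rule set must be non-empty")
  nl <- neutral_losses(spec, tol = loss_tol)
  rows <- lapply(rules, function(r) {
    req <- r$fragments[r$fragments$role == "required", , drop = FALSE]
    forb <- r$fragments[r$fragments$role == "forbidden", , drop = FALSE]
    have_frag <- vapply(req$mz, function(m) any(abs(spec$mz - m) <= frag_tol),
                        logical(1))
    have_loss <- vapply(r$losses, function(f) f %in% nl$loss_formula, logical(1))
    forbidden <- if (nrow(forb)) any(vapply(forb$mz, function(m)
      any(abs(spec$mz - m) <= frag_tol), logical(1))) else FALSE
    matched <- c(if (any(have_frag)) paste0("frag:", req$formula[have_frag]),
                 if (any(have_loss)) paste0("loss:", r$losses[have_loss]))
    data.frame(class_label = r$class_label,
               matched = paste(matched, collapse = ";"),
               n_matched = length(matched),
               forbidden_present = forbidden,
               satisfied = length(matched) >= r$min_matches && !forbidden,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble annotation evidence for a feature
#'
#' @param feature_id Feature label.
#' @param library_hits Data frame from [library_search()].
#' @param suspect_hits Data frame from [suspect_screen()].
#' @param class_evidence Data frame from [classify_by_fragments()].
#' @param has_reference_standard_match Reference standard measured with
#'   matching RT and MS/MS.
#' @param isomer_ambiguity Multiple indistinguishable (e.g. positional)
#'   isomer candidates remain.
#' @param structure_known Candidate structure previously reported (library,
#'   suspect list or literature) rather than newly proposed.
#' @param formula_unequivocal Elemental composition confirmed (isotopes,
#'   RDB) but no structural evidence.
#' @return An object of class `annotation_evidence`.
#' @export
annotation_evidence <- function(feature_id,
                                library_hits = .empty_hits_df(),
                                suspect_hits = NULL,
                                class_evidence = NULL,
                                has_reference_standard_match = FALSE,
                                isomer_ambiguity = FALSE,
                                structure_known = TRUE,
                                formula_unequivocal = FALSE) {
  structure(list(
    feature_id = feature_id,
    library_hits = library_hits,
    suspect_hits = suspect_hits,
    class_evidence = class_evidence,
    has_reference_standard_match = isTRUE(has_reference_standard_match),
    isomer_ambiguity = isTRUE(isomer_ambiguity),
    structure_known = isTRUE(structure_known),
    formula_unequivocal = isTRUE(formula_unequivocal),
    confidence = NA_character_
  ), class = "annotation_evidence")
}

#' Assign a PFAS identification confidence level
#'
#' Deterministic decision ladder over the recorded evidence, following the
#' PFAS adaptation of the Schymanski identification-confidence scale:
#' \describe{
#'   \item{1a}{library MS/MS hit confirmed by a reference standard
#'     (matching RT).}
#'   \item{1b}{library MS/MS hit indistinguishable from the standard class
#'     spectrum, no RT-matched standard in hand.}
#'   \item{2a}{diagnostic fragmentation evidence for a unique, previously
#'     reported structure; no standard available.}
#'   \item{2b}{diagnostic fragmentation evidence without isomer
#'     discrimination but a single plausible literature structure.}
#'   \item{3a}{MS/MS consistent with the annotation but positional isomer
#'     candidates remain.}
#'   \item{3b}{structure newly proposed from fragmentation evidence alone.}
#'   \item{4}{unequivocal molecular formula, no structural evidence.}
#'   \item{5a}{suspect exact-mass match only.}
#'   \item{5b}{non-target exact mass of interest only (including suspect
#'     matches that cannot be resolved among isomer candidates).}
#' }
#' Downgrading any evidence item never raises the level.
#'
#' @param evidence An `annotation_evidence` object.
#' @return The evidence object with `confidence` set and a `justification`
#'   attribute on the level.
#' @export
assign_confidence <- function(evidence) {
  stopifnot(inherits(evidence, "annotation_evidence"))
  has_lib <- !is.null(evidence$library_hits) && nrow(evidence$library_hits) > 0
  has_suspect <- !is.null(evidence$suspect_hits) && nrow(evidence$suspect_hits) > 0
  has_diag <- !is.null(evidence$class_evidence) &&
    any(evidence$class_evidence$satisfied)
  level <- if (has_lib && evidence$has_reference_standard_match) {
    c("1a", "library hit confirmed by reference standard")
  } else if (has_lib) {
    c("1b", "library MS/MS match, no reference standard RT")
  } else if (has_diag && evidence$isomer_ambiguity) {
    c("3a", "diagnostic MS/MS with positional isomer candidates")
  } else if (has_diag && evidence$structure_known) {
    c("2a", "diagnostic fragmentation evidence, unique reported structure")
  } else if (has_diag) {
    c("3b", "structure proposed from fragmentation evidence alone")
  } else if (evidence$formula_unequivocal) {
    c("4", "unequivocal molecular formula, no structure")
  } else if (has_suspect && !evidence$isomer_ambiguity) {
    c("5a", "suspect exact-mass match only")
  } else {
    c("5b", "exact mass of interest only")
  }
  evidence$confidence <- level[1]
  attr(evidence$confidence, "justification") <- level[2]
  evidence
}

#' @export
print.annotation_evidence <- function(x, ...) {
  cat("<annotation_evidence>", x$feature_id, "\n")
  cat("  library hits: ", if (is.null(x$library_hits)) 0 else nrow(x$library_hits),
      " | suspect hits: ", if (is.null(x$suspect_hits)) 0 else nrow(x$suspect_hits),
      "\n", sep = "")
  if (!is.null(x$class_evidence) && any(x$class_evidence$satisfied))
    cat("  class evidence:",
        paste(x$class_evidence$class_label[x$class_evidence$satisfied],
              collapse = ", "), "\n")
  if (!is.na(x$confidence))
    cat("  confidence:", x$confidence,
        paste0("(", attr(x$confidence, "justification"), ")"), "\n")
  invisible(x)
}
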