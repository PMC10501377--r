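#' Attach MS/MS spectra to aligned features
#'
#' Spectra read from MGF (or generated synthetically) are keyed by an id.
#' When features carry a matching `source_id` the link is direct; otherwise
#' spectra are matched by precursor m/z within `mz_tol` of the feature
#' consensus m/z (closest feature wins).
#'
#' @param x An `nta_features` (or `nta_prioritized`) object.
#' @param spectra Named list: id -> list of `ms2_spectrum`.
#' @param mz_tol Precursor matching tolerance (Da) for m/z-based linking.
#' @return `x` with its `spectra` slot filled (feature_id -> list of
#'   spectra).
#' @export
attach_spectra <- function(x, spectra, mz_tol = 0.02) {
  stopifnot(inherits(x, "nta_features"))
  out <- x$spectra
  by_source <- intersect(names(spectra), x$features$source_id)
  for (id in names(spectra)) {
    if (id %in% by_source) {
      fid <- x$features$feature_id[match(id, x$features$source_id)]
    } else {
      prec <- spectra[[id]][[1]]$precursor_mz
      d <- abs(x$features$mz - prec)
      if (min(d) > mz_tol) next
      fid <- x$features$feature_id[which.min(d)]
    }
    out[[fid]] <- c(out[[fid]], spectra[[id]])
  }
  x$spectra <- out
  x
}

#' Annotate prioritized features
#'
#' Runs, for every surviving feature: spectral-library search (when a
#' library is supplied), suspect screening, diagnostic-fragment
#' classification of its MS/MS spectra, homologue-series RT consistency,
#' and confidence-level assignment.
#'
#' @param prioritized An `nta_prioritized` object with spectra attached.
#' @param suspects Optional suspect data frame (see [suspect_screen()]).
#' @param library Optional spectral library (see [library_search()]).
#' @param rules Fragment rules (default [fragment_rules()]).
#' @param series Optional `homologue_series_list` used for the RT
#'   consistency flag of library hits.
#' @param reference_standards Character vector of library entry names for
#'   which a reference standard was run (enables level 1a).
#' @param frag_tol Fragment tolerance (Da).
#' @return List of class `nta_annotations`: per-feature
#'   `annotation_evidence` objects (with confidence assigned) plus a
#'   `summary` data frame.
#' @export
annotate_features <- function(prioritized, suspects = NULL, library = NULL,
                              rules = fragment_rules(), series = NULL,
                              reference_standards = character(0),
                              frag_tol = 0.01) {
  stopifnot(inherits(prioritized, "nta_prioritized"))
  feats <- prioritized$features
  keep <- feats$feature_id %in% prioritized$survivors
  feats <- feats[keep, , drop = FALSE]
  evidence <- list()
  for (i in seq_len(nrow(feats))) {
    fid <- feats$feature_id[i]
    sps <- prioritized$spectra[[fid]] %||% list()
    rt_ok <- TRUE
    if (!is.null(series)) {
      for (s in series) {
        if (fid %in% s$members && !any(is.na(s$rt)))
          rt_ok <- rt_ok && series_rt_consistency(s)
      }
    }
    lib_hits <- if (!is.null(library))
      library_search(feats$mz[i], sps, library, rt_consistent = rt_ok,
                     frag_tol = frag_tol) else NULL
    sus_hits <- if (!is.null(suspects))
      suspect_screen(feats$mz[i], suspects) else NULL
    cls <- if (length(sps))
      classify_by_fragments(sps[[1]], rules, frag_tol = frag_tol) else NULL
    ref_match <- !is.null(lib_hits) && nrow(lib_hits) > 0 &&
      any(lib_hits$name %in% reference_standards)
    ev <- annotation_evidence(
      feature_id = fid,
      library_hits = lib_hits %||% .empty_hits_df(),
      suspect_hits = sus_hits,
      class_evidence = cls,
      has_reference_standard_match = ref_match
    )
    evidence[[fid]] <- assign_confidence(ev)
  }
  summary <- data.frame(
    feature_id = feats$feature_id,
    mz = feats$mz,
    rt_min = feats$rt,
    kmd = feats$kmd,
    n_spectra = vapply(feats$feature_id, function(f)
      length(prioritized$spectra[[f]] %||% list()), integer(1)),
    best_library_hit = vapply(evidence, function(e)
      if (nrow(e$library_hits)) e$library_hits$name[1] else NA_character_,
      character(1)),
    best_suspect_hit = vapply(evidence, function(e)
      if (!is.null(e$suspect_hits) && nrow(e$suspect_hits))
        e$suspect_hits$name[1] else NA_character_, character(1)),
    class_call = vapply(evidence, function(e) {
      if (is.null(e$class_evidence)) return(NA_character_)
      s <- e$class_evidence$class_label[e$class_evidence$satisfied]
      if (length(s)) paste(s, collapse = ";") else NA_character_
    }, character(1)),
    confidence = vapply(evidence, function(e) as.character(e$confidence),
                        character(1)),
    stringsAsFactors = FALSE
  )
  rownames(summary) <- NULL
  structure(list(evidence = evidence, summary = summary),
            class = "nta_annotations")
}

#' @export
print.nta_annotations <- function(x, ...) {
  cat("<nta_annotations> ", nrow(x$summary), " features\n", sep = "")
  print(table(confidence = x$summary$confidence))
  invisible(x)
}

#' Run the complete screening workflow on a dataset
#'
#' Convenience wrapper: align, prioritize, detect homologue series among
#' survivors, attach MS/MS spectra and annotate. This is the programmatic
#' equivalent of the command-line `all` subcommand.
#'
#' @param observations Observation data frame.
#' @param spectra Named spectra list (optional).
#' @param suspects Suspect data frame (optional).
#' @param library Spectral library (optional).
#' @param cfg A [pipeline_config()].
#' @param ... Passed to [annotate_features()].
#' @return List of class `nta_run`: `features`, `prioritized`, `series`,
#'   `annotations`, `provenance`.
#' @export
run_workflow <- function(observations, spectra = NULL, suspects = NULL,
                         library = NULL, cfg = pipeline_config(), ...) {
  feats <- align_observations(observations, cfg)
  if (!is.null(spectra)) feats <- attach_spectra(feats, spectra, cfg$mz_tol)
  pri <- prioritize(feats, cfg)
  series <- detect_series(pri)
  ann <- annotate_features(pri, suspects = suspects, library = library,
                           series = series, ...)
  prov <- list(
    config_hash = .config_hash(cfg),
    n_observations = nrow(observations),
    stage_counts = as.list(pri$counts),
    n_series = length(series),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  structure(list(features = feats, prioritized = pri, series = series,
                 annotations = ann, provenance = prov),
            class = "nta_run")
}

#' @export
print.nta_run <- function(x, ...) {
  print(x$prioritized)
  cat("homologue series:", length(x$series), "\n")
  print(x$annotations)
  invisible(x)
}
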