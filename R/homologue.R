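#' Detect homologous series in (m/z, KMD) space
#'
#' Finds groups of features spaced by integer multiples of a repeating unit
#' (CF2 by default) that share a Kendrick mass defect -- the algorithmic
#' equivalent of spotting horizontally adjacent points in a KMD plot.
#' Candidate pairs are linked when their m/z difference is within
#' `mz_tol * k` of `k` repeat units (k >= 1) and their KMDs differ by at
#' most `2 * kmd_tol`; connected components are then pruned until every
#' member's KMD lies within `kmd_tol` of the component mean (worst offender
#' removed first, ties broken by higher m/z), and components smaller than
#' `min_members` are dropped. Output ordering is deterministic: by mean KMD,
#' then by lowest member m/z.
#'
#' @param features Data frame with columns `feature_id`, `mz` and optionally
#'   `kmd` (computed with [kendrick()] when absent); an `nta_features`
#'   object is also accepted (survivors only for `nta_prioritized`).
#' @param unit Repeat unit as a formula string or `formula_counts`
#'   (default CF2; C2F4, CH2 and C2H4O are common alternatives).
#' @param kmd_tol KMD coherence tolerance (Da, default 0.005).
#' @param mz_tol Spacing tolerance per unit step (Da, default 0.01).
#' @param min_members Minimum series size (default 2).
#' @return A list of class `homologue_series_list`; each element is a
#'   `homologue_series` with fields `unit` (formula string), `unit_mass`,
#'   `members` (feature ids by ascending m/z), `mz`, `kmd`,
#'   `unit_counts` (integer spacing between consecutive members) and
#'   `mean_kmd`.
#' @export
detect_series <- function(features, unit = "CF2", kmd_tol = 0.005,
                          mz_tol = 0.01, min_members = 2) {
  if (min_members < 2) stop("min_members must be at least 2")
  feats <- .series_feature_table(features)
  n <- nrow(feats)
  unit_f <- .as_formula(unit)
  unit_mass <- monoisotopic_mass(unit_f)
  if (n < min_members) return(.empty_series_list())

  ord <- order(feats$mz)
  feats <- feats[ord, , drop = FALSE]

  # adjacency by unit spacing + pairwise KMD agreement
  adj <- vector("list", n)
  for (i in seq_len(n - 1)) {
    dmz <- feats$mz[(i + 1):n] - feats$mz[i]
    k <- round(dmz / unit_mass)
    ok <- k >= 1 & abs(dmz - k * unit_mass) <= mz_tol * pmax(k, 1) &
      abs(feats$kmd[(i + 1):n] - feats$kmd[i]) <= 2 * kmd_tol
    js <- which(ok) + i
    adj[[i]] <- c(adj[[i]], js)
    for (j in js) adj[[j]] <- c(adj[[j]], i)
  }

  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cid
      queue <- c(queue, adj[[v]][comp[adj[[v]]] == 0L])
    }
  }

  series <- list()
  for (g in seq_len(cid)) {
    idx <- which(comp == g)
    # KMD-coherence pruning against the running mean
    repeat {
      if (length(idx) < min_members) break
      dev <- abs(feats$kmd[idx] - mean(feats$kmd[idx]))
      if (max(dev) <= kmd_tol) break
      worst <- idx[order(-dev, -feats$mz[idx])][1]
      idx <- setdiff(idx, worst)
    }
    if (length(idx) < min_members) next
    idx <- idx[order(feats$mz[idx])]
    spacing <- as.integer(round(diff(feats$mz[idx]) / unit_mass))
    series[[length(series) + 1L]] <- structure(list(
      unit = format_formula(unit_f),
      unit_mass = unit_mass,
      members = feats$feature_id[idx],
      mz = feats$mz[idx],
      rt = if ("rt" %in% names(feats)) feats$rt[idx] else rep(NA_real_, length(idx)),
      kmd = feats$kmd[idx],
      unit_counts = spacing,
      mean_kmd = mean(feats$kmd[idx])
    ), class = "homologue_series")
  }
  o <- order(vapply(series, `[[`, numeric(1), "mean_kmd"),
             vapply(series, function(s) s$mz[1], numeric(1)))
  structure(series[o], class = "homologue_series_list")
}

.series_feature_table <- function(features) {
  if (inherits(features, "nta_prioritized")) {
    keep <- features$features$feature_id %in% features$survivors
    features <- features$features[keep, , drop = FALSE]
  } else if (inherits(features, "nta_features")) {
    features <- features$features
  }
  if (!all(c("feature_id", "mz") %in% names(features)))
    stop("features must carry feature_id and mz columns")
  if (!"kmd" %in% names(features)) features$kmd <- kendrick(features$mz)$kmd
  features
}

.empty_series_list <- function() structure(list(), class = "homologue_series_list")

#' @export
print.homologue_series <- function(x, ...) {
  cat("<homologue_series> unit ", x$unit,
      sprintf(" | %d members | mean KMD %+.4f\n", length(x$members), x$mean_kmd),
      sep = "")
  cat("  m/z:", paste(sprintf("%.4f", x$mz), collapse = " -> "), "\n")
  cat("  spacing (units):", paste(x$unit_counts, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.homologue_series_list <- function(x, ...) {
  cat("<homologue_series_list> ", length(x), " series\n", sep = "")
  for (s in x) print(s)
  invisible(x)
}

#' Validate the structural invariants of a homologue series
#'
#' Re-checks, independently of the detection algorithm, that a series has
#' at least two members, consecutive m/z gaps within tolerance of
#' `unit_counts * unit_mass`, and all member KMDs within `kmd_tol` of the
#' series mean.
#'
#' @param series A `homologue_series`.
#' @param kmd_tol,mz_tol Tolerances as in [detect_series()].
#' @return TRUE, or FALSE with attribute `reason`.
#' @export
validate_series <- function(series, kmd_tol = 0.005, mz_tol = 0.01) {
  fail <- function(msg) structure(FALSE, reason = msg)
  if (length(series$members) < 2) return(fail("fewer than 2 members"))
  gaps <- diff(series$mz)
  expect <- series$unit_counts * series$unit_mass
  if (any(abs(gaps - expect) > mz_tol * pmax(series$unit_counts, 1)))
    return(fail("spacing outside tolerance"))
  if (any(abs(series$kmd - series$mean_kmd) > kmd_tol))
    return(fail("KMD incoherent"))
  TRUE
}

#' Retention-time consistency of a homologue series
#'
#' Under the reversed-phase convention, retention time must increase with
#' homologue mass. The check passes when each member elutes later than its
#' lighter neighbour, up to a slack of `slack` minutes per repeat unit
#' (slack 0 means strictly increasing; equal RTs then fail).
#'
#' @param series A `homologue_series` whose members carry RT values, or a
#'   series plus a `features` table with `feature_id` and `rt` columns.
#' @param features Optional feature table supplying RTs.
#' @param slack Allowed RT slack per unit step (minutes, default 0).
#' @return TRUE or FALSE.
#' @export
series_rt_consistency <- function(series, features = NULL, slack = 0) {
  rt <- series$rt
  if (!is.null(features)) {
    tab <- .series_feature_table(features)
    if (!"rt" %in% names(tab)) stop("features table lacks an rt column")
    rt <- tab$rt[match(series$members, tab$feature_id)]
  }
  if (any(is.na(rt))) stop("series members lack retention times")
  if (length(rt) < 2) stop("series must have at least 2 members with RT")
  all(diff(rt) > -slack * series$unit_counts)
}

#' Export a KMD plot table
#'
#' @param features Feature table or `nta_features` object.
#' @param series Optional `homologue_series_list` used to label members.
#' @return Data frame with `feature_id`, `mz`, `kmd`, `series_id` (NA when
#'   unassigned), suitable for external plotting of KMD vs m/z.
#' @export
kmd_plot_table <- function(features, series = NULL) {
  tab <- .series_feature_table(features)
  out <- data.frame(feature_id = tab$feature_id, mz = tab$mz, kmd = tab$kmd,
                    series_id = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(series)) {
    for (i in seq_along(series))
      out$series_id[out$feature_id %in% series[[i]]$members] <-
        sprintf("S%02d", i)
  }
  out
}
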