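#' Pipeline configuration
#'
#' Thresholds and tolerances for feature alignment and the prioritization
#' cascade. Defaults follow the negative-mode PFAS screening settings used
#' throughout this package: XIC-style alignment at 0.02 Da / 30 s, a
#' 5000 cps detection floor, replicate RSD < 20 %, intensity > 10 x the
#' procedural blank, retention time 1-13 min, Kendrick mass defect within
#' -0.15..0.15, and case-control selection at log2 fold change > 0.9 and
#' p < 0.05 (Welch t-test on log2 intensities).
#'
#' @param mz_tol m/z alignment tolerance (Da).
#' @param rt_tol RT alignment tolerance (seconds).
#' @param min_intensity Detection floor applied at observation ingestion (cps).
#' @param rsd_max Maximum replicate relative standard deviation (percent,
#'   strict `<`).
#' @param blank_factor Required ratio of case mean to maximum blank
#'   intensity (strict `>`).
#' @param rt_window Retention-time window in minutes, inclusive.
#' @param kmd_window Kendrick-mass-defect window in Da, inclusive.
#' @param lfc_min Minimum log fold change (strict `>`), in units of
#'   `log_base`.
#' @param p_max Maximum t-test p-value (strict `<`).
#' @param imputation_floor Zeros are imputed as this fraction of the
#'   smallest positive intensity in the table before log transformation.
#' @param log_base Base of the fold-change logarithm (default 2).
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` (the default) applies raw p-values.
#' @param blank_groups Group labels treated as procedural blanks.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mz_tol = 0.02, rt_tol = 30, min_intensity = 5000,
                            rsd_max = 20, blank_factor = 10,
                            rt_window = c(1, 13),
                            kmd_window = c(-0.15, 0.15),
                            lfc_min = 0.9, p_max = 0.05,
                            imputation_floor = 0.5, log_base = 2,
                            p_adjust = "none",
                            blank_groups = c("blank", "solvent_blank")) {
  if (mz_tol <= 0 || rt_tol <= 0) stop("alignment tolerances must be positive")
  if (rsd_max <= 0 || blank_factor <= 0) stop("thresholds must be positive")
  if (length(rt_window) != 2 || rt_window[1] > rt_window[2])
    stop("rt_window must be an ordered pair")
  if (length(kmd_window) != 2 || kmd_window[1] > kmd_window[2])
    stop("kmd_window must be an ordered pair")
  if (imputation_floor <= 0 || log_base <= 1) stop("invalid imputation/log settings")
  structure(list(
    mz_tol = mz_tol, rt_tol = rt_tol, min_intensity = min_intensity,
    rsd_max = rsd_max, blank_factor = blank_factor,
    rt_window = rt_window, kmd_window = kmd_window,
    lfc_min = lfc_min, p_max = p_max,
    imputation_floor = imputation_floor, log_base = log_base,
    p_adjust = p_adjust, blank_groups = blank_groups
  ), class = "pipeline_config")
}

.injection_id <- function(sample_id, replicate) paste(sample_id, replicate, sep = ":")

.check_observations <- function(obs) {
  need <- c("mz", "rt", "intensity", "sample_id", "replicate", "group")
  miss <- setdiff(need, names(obs))
  if (length(miss)) stop("observation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(obs) && (any(obs$mz <= 0) || any(obs$rt < 0) || any(obs$intensity < 0)))
    stop("observations must satisfy mz > 0, rt >= 0, intensity >= 0")
  invisible(obs)
}

#' Align feature observations across injections
#'
#' Greedy intensity-seeded clustering: observations are visited in order of
#' decreasing intensity (ties broken by ascending m/z) and attached to the
#' first existing cluster whose seed lies within `mz_tol` and `rt_tol`;
#' otherwise they seed a new cluster. The result is deterministic and
#' independent of input row order. Consensus m/z and RT are
#' intensity-weighted means; the per-injection intensity is the maximum of
#' that injection's member observations (0 when not detected).
#'
#' @param obs Data frame of observations with columns `mz`, `rt` (minutes),
#'   `intensity`, `sample_id`, `replicate`, `group`, and optionally
#'   `source_id` (propagated by majority vote, used by the synthetic-data
#'   ground truth).
#' @param cfg A [pipeline_config()].
#' @return An object of class `nta_features`: list with `features` (data
#'   frame: feature_id, mz, rt, kendrick columns), `intensities` (feature x
#'   injection matrix), `design` (injection table) and `spectra` (named
#'   list, empty until attached).
#' @export
align_observations <- function(obs, cfg = pipeline_config()) {
  .check_observations(obs)
  obs <- obs[obs$intensity >= cfg$min_intensity | obs$group %in% cfg$blank_groups, ,
             drop = FALSE]
  design <- unique(data.frame(
    sample_id = obs$sample_id, replicate = obs$replicate, group = obs$group,
    stringsAsFactors = FALSE
  ))
  design$injection_id <- .injection_id(design$sample_id, design$replicate)
  design <- design[order(design$group, design$sample_id, design$replicate), ]
  rownames(design) <- NULL

  if (nrow(obs) == 0) {
    return(.new_nta_features(
      data.frame(feature_id = character(0), mz = numeric(0), rt = numeric(0)),
      matrix(0, 0, nrow(design), dimnames = list(NULL, design$injection_id)),
      design))
  }

  ord <- order(-obs$intensity, obs$mz, obs$rt)
  obs <- obs[ord, , drop = FALSE]
  rt_tol_min <- cfg$rt_tol / 60
  n <- nrow(obs)
  seed_mz <- numeric(n); seed_rt <- numeric(n); n_seed <- 0L
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    if (n_seed > 0L) {
      dmz <- abs(seed_mz[seq_len(n_seed)] - obs$mz[i])
      drt <- abs(seed_rt[seq_len(n_seed)] - obs$rt[i])
      ok <- which(dmz <= cfg$mz_tol & drt <= rt_tol_min)
      if (length(ok)) hit <- ok[which.min(dmz[ok])]
    }
    if (hit == 0L) {
      n_seed <- n_seed + 1L
      seed_mz[n_seed] <- obs$mz[i]
      seed_rt[n_seed] <- obs$rt[i]
      hit <- n_seed
    }
    assign[i] <- hit
  }

  inj <- .injection_id(obs$sample_id, obs$replicate)
  cons_mz <- tapply(obs$mz * obs$intensity, assign, sum) /
    tapply(obs$intensity, assign, sum)
  cons_rt <- tapply(obs$rt * obs$intensity, assign, sum) /
    tapply(obs$intensity, assign, sum)
  # fall back to plain means for all-zero-intensity clusters
  zi <- !is.finite(cons_mz)
  if (any(zi)) {
    cons_mz[zi] <- tapply(obs$mz, assign, mean)[zi]
    cons_rt[zi] <- tapply(obs$rt, assign, mean)[zi]
  }

  k <- n_seed
  feat_ord <- order(cons_mz, cons_rt)
  rank <- integer(k); rank[feat_ord] <- seq_len(k)
  ids <- sprintf("F%05d", rank)

  intens <- matrix(0, nrow = k, ncol = nrow(design),
                   dimnames = list(ids, design$injection_id))
  col <- match(inj, design$injection_id)
  for (i in seq_len(nrow(obs))) {
    r <- assign[i]
    intens[r, col[i]] <- max(intens[r, col[i]], obs$intensity[i])
  }

  src <- rep(NA_character_, k)
  if ("source_id" %in% names(obs)) {
    src <- vapply(seq_len(k), function(j) {
      s <- obs$source_id[assign == j]
      s <- s[!is.na(s)]
      if (!length(s)) return(NA_character_)
      names(sort(table(s), decreasing = TRUE))[1]
    }, character(1))
  }

  features <- data.frame(
    feature_id = ids, mz = as.numeric(cons_mz), rt = as.numeric(cons_rt),
    n_obs = as.integer(table(assign)), source_id = src,
    stringsAsFactors = FALSE
  )
  features <- features[order(features$mz, features$rt), ]
  intens <- intens[features$feature_id, , drop = FALSE]
  rownames(features) <- NULL
  .new_nta_features(features, intens, design)
}

.new_nta_features <- function(features, intensities, design, spectra = list()) {
  kv <- if (nrow(features)) kendrick(features$mz) else
    data.frame(kendrick_mass = numeric(0), nominal_kendrick_mass = integer(0),
               kmd = numeric(0))
  features$kendrick_mass <- kv$kendrick_mass
  features$nominal_kendrick_mass <- kv$nominal_kendrick_mass
  features$kmd <- kv$kmd
  structure(list(features = features, intensities = intensities,
                 design = design, spectra = spectra),
            class = "nta_features")
}

#' @export
print.nta_features <- function(x, ...) {
  cat("<nta_features> ", nrow(x$features), " features x ",
      nrow(x$design), " injections (",
      paste(sprintf("%s: %d", names(table(x$design$group)),
                    as.integer(table(x$design$group))), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

.group_cols <- function(x, groups) {
  x$design$injection_id[x$design$group %in% groups]
}

#' Relative standard deviation (percent)
#' @param x Numeric vector of intensities.
#' @return `sd(x) / mean(x) * 100`.
#' @export
rsd <- function(x) stats::sd(x) / mean(x) * 100

#' Replicate-reproducibility (RSD) filter
#'
#' A feature passes when it is present (intensity > 0) in every case-group
#' injection and the relative standard deviation of those intensities is
#' strictly below `rsd_max`.
#'
#' @param x An `nta_features` object.
#' @param cfg A [pipeline_config()].
#' @param group Group whose replicates are assessed (default `"case"`).
#' @return Named logical vector, one element per feature.
#' @export
replicate_rsd_filter <- function(x, cfg = pipeline_config(), group = "case") {
  cols <- .group_cols(x, group)
  if (length(cols) < 2) stop("RSD undefined: fewer than 2 replicate injections in group ",
                             sQuote(group))
  m <- x$intensities[, cols, drop = FALSE]
  present <- apply(m > 0, 1, all)
  rsds <- apply(m, 1, rsd)
  pass <- present & !is.na(rsds) & rsds < cfg$rsd_max
  stats::setNames(pass, x$features$feature_id)
}

#' Procedural-blank ratio filter
#'
#' Passes when the case-group mean intensity is strictly greater than
#' `blank_factor` times the maximum intensity observed in any blank
#' injection. Features absent from all blanks pass whenever their case mean
#' is positive.
#'
#' @inheritParams replicate_rsd_filter
#' @return Named logical vector.
#' @export
blank_filter <- function(x, cfg = pipeline_config(), group = "case") {
  case_cols <- .group_cols(x, group)
  blank_cols <- .group_cols(x, cfg$blank_groups)
  case_mean <- rowMeans(x$intensities[, case_cols, drop = FALSE])
  blank_max <- if (length(blank_cols))
    apply(x$intensities[, blank_cols, drop = FALSE], 1, max) else
      rep(0, nrow(x$features))
  pass <- ifelse(blank_max == 0, case_mean > 0,
                 case_mean > cfg$blank_factor * blank_max)
  stats::setNames(pass, x$features$feature_id)
}

#' Retention-time window filter (inclusive bounds)
#' @inheritParams replicate_rsd_filter
#' @return Named logical vector.
#' @export
rt_window_filter <- function(x, cfg = pipeline_config()) {
  pass <- x$features$rt >= cfg$rt_window[1] & x$features$rt <= cfg$rt_window[2]
  stats::setNames(pass, x$features$feature_id)
}

#' Kendrick-mass-defect window filter (inclusive bounds)
#' @inheritParams replicate_rsd_filter
#' @return Named logical vector.
#' @export
kmd_window_filter <- function(x, cfg = pipeline_config()) {
  pass <- x$features$kmd >= cfg$kmd_window[1] & x$features$kmd <= cfg$kmd_window[2]
  stats::setNames(pass, x$features$feature_id)
}

#' Welch two-sample t-test on log-transformed intensities
#'
#' Workhorse behind [case_control_stats()], exposed for direct use on
#' intensity vectors. Zeros are imputed as `floor_value` before the log
#' transform; the fold change is the difference of group means on the log
#' scale.
#'
#' @param case,control Numeric intensity vectors (length >= 2 each).
#' @param floor_value Imputation value substituted for zeros.
#' @param log_base Logarithm base (default 2).
#' @return List with `log_fold_change`, `p_value`, `case_mean`,
#'   `control_mean` (means on the raw intensity scale, after imputation).
#' @export
welch_log_test <- function(case, control, floor_value = NULL, log_base = 2) {
  if (length(case) < 2 || length(control) < 2)
    stop("need at least 2 case and 2 control intensities")
  if (is.null(floor_value)) {
    pos <- c(case, control); pos <- pos[pos > 0]
    floor_value <- if (length(pos)) 0.5 * min(pos) else 1
  }
  case[case <= 0] <- floor_value
  control[control <= 0] <- floor_value
  lx <- log(case, base = log_base)
  ly <- log(control, base = log_base)
  m1 <- mean(lx); m2 <- mean(ly)
  v1 <- stats::var(lx); v2 <- stats::var(ly)
  n1 <- length(lx); n2 <- length(ly)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    p <- if (m1 == m2) 1 else 0
  } else {
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  list(log_fold_change = m1 - m2, p_value = p,
       case_mean = mean(case), control_mean = mean(control))
}

#' Case-control statistics for every feature
#'
#' Intensities are imputed (zeros replaced by `imputation_floor` times the
#' smallest positive intensity in the whole table), averaged per sample so
#' that biological samples -- not replicate injections -- are the
#' statistical units, log-transformed, and compared by Welch's
#' unequal-variance t-test. The log fold change is
#' `mean(log2 case) - mean(log2 control)`.
#'
#' @inheritParams replicate_rsd_filter
#' @return Data frame with columns `feature_id`, `log_fold_change`,
#'   `p_value`, `case_mean`, `control_mean`.
#' @export
case_control_stats <- function(x, cfg = pipeline_config()) {
  case_design <- x$design[x$design$group == "case", ]
  ctrl_design <- x$design[x$design$group == "control", ]
  if (nrow(case_design) == 0 || nrow(ctrl_design) == 0)
    stop("design must contain both case and control injections")
  pos <- x$intensities[x$intensities > 0]
  floor_value <- if (length(pos)) cfg$imputation_floor * min(pos) else 1
  m <- x$intensities
  m[m <= 0] <- floor_value
  per_sample <- function(design_rows) {
    ids <- unique(design_rows$sample_id)
    sapply(ids, function(s) {
      cols <- design_rows$injection_id[design_rows$sample_id == s]
      rowMeans(m[, cols, drop = FALSE])
    })
  }
  case_m <- per_sample(case_design)
  ctrl_m <- per_sample(ctrl_design)
  if (ncol(case_m) < 2 || ncol(ctrl_m) < 2)
    stop("need at least 2 case and 2 control samples")
  res <- lapply(seq_len(nrow(x$features)), function(i)
    welch_log_test(case_m[i, ], ctrl_m[i, ], floor_value = floor_value,
                   log_base = cfg$log_base))
  out <- data.frame(
    feature_id = x$features$feature_id,
    log_fold_change = vapply(res, `[[`, numeric(1), "log_fold_change"),
    p_value = vapply(res, `[[`, numeric(1), "p_value"),
    case_mean = vapply(res, `[[`, numeric(1), "case_mean"),
    control_mean = vapply(res, `[[`, numeric(1), "control_mean"),
    stringsAsFactors = FALSE
  )
  if (cfg$p_adjust != "none")
    out$p_value <- stats::p.adjust(out$p_value, method = cfg$p_adjust)
  out
}

#' Run the full feature-prioritization cascade
#'
#' Applies, in order: replicate RSD filter, procedural-blank ratio filter,
#' retention-time window, Kendrick-mass-defect window, and case-control
#' selection (log fold change > `lfc_min` and p < `p_max`). All filters are
#' independent predicates, so the surviving set equals the intersection of
#' the individual pass sets; the staged counts report how many features
#' remain after each step in cascade order.
#'
#' @param x An `nta_features` object.
#' @param cfg A [pipeline_config()].
#' @return An object of class `nta_prioritized`: the input plus `flags`
#'   (per-filter logical matrix), `stats` (case-control statistics),
#'   `survivors` (character vector of surviving feature ids), `counts`
#'   (features remaining after each stage) and `cfg`.
#' @export
prioritize <- function(x, cfg = pipeline_config()) {
  stopifnot(inherits(x, "nta_features"))
  if (!all(c("case", "control") %in% x$design$group))
    stop("design must contain 'case' and 'control' groups")
  st <- case_control_stats(x, cfg)
  flags <- cbind(
    rsd = replicate_rsd_filter(x, cfg),
    blank = blank_filter(x, cfg),
    rt_window = rt_window_filter(x, cfg),
    kmd_window = kmd_window_filter(x, cfg),
    case_control = st$log_fold_change > cfg$lfc_min & st$p_value < cfg$p_max
  )
  rownames(flags) <- x$features$feature_id
  cum <- rep(TRUE, nrow(flags))
  counts <- c(input = nrow(flags))
  for (f in colnames(flags)) {
    cum <- cum & flags[, f]
    counts[f] <- sum(cum)
  }
  structure(list(
    features = x$features, intensities = x$intensities, design = x$design,
    spectra = x$spectra, flags = flags, stats = st,
    survivors = x$features$feature_id[cum], counts = counts, cfg = cfg
  ), class = c("nta_prioritized", "nta_features"))
}

#' @export
print.nta_prioritized <- function(x, ...) {
  cat("<nta_prioritized>\n")
  stages <- names(x$counts)
  for (i in seq_along(stages))
    cat(sprintf("  %-14s %6d features\n", stages[i], x$counts[i]))
  invisible(x)
}

#' @export
summary.nta_prioritized <- function(object, ...) {
  cat("Feature prioritization cascade\n")
  print(object)
  cat("\nSurvivors:\n")
  print(utils::head(survivor_report(object), 20))
  invisible(object)
}

#' Survivor report table
#'
#' @param x An `nta_prioritized` object.
#' @param survivors_only Keep only features passing the full cascade
#'   (default TRUE).
#' @return Data frame with feature id, m/z, RT, KMD, per-filter pass flags,
#'   log fold change and p-value.
#' @export
survivor_report <- function(x, survivors_only = TRUE) {
  stopifnot(inherits(x, "nta_prioritized"))
  out <- data.frame(
    feature_id = x$features$feature_id,
    mz = x$features$mz,
    rt_min = x$features$rt,
    kmd = x$features$kmd,
    x$flags,
    log2fc = x$stats$log_fold_change,
    p_value = x$stats$p_value,
    stringsAsFactors = FALSE
  )
  if (survivors_only) out <- out[out$feature_id %in% x$survivors, ]
  rownames(out) <- NULL
  out
}
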