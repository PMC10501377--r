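# Shared builders for small in-code fixtures.

# Config suitable for hand-built miniature tables (no detection floor).
tiny_cfg <- function(...) pipeline_config(min_intensity = 0, ...)

# A minimal case/control/blank design: 2 case and 2 control samples in
# triplicate plus duplicate blank injections.
tiny_design <- function() {
  rbind(
    expand.grid(sample_id = c("case1", "case2"), replicate = 1:3,
                group = "case", stringsAsFactors = FALSE),
    expand.grid(sample_id = c("ctrl1", "ctrl2"), replicate = 1:3,
                group = "control", stringsAsFactors = FALSE),
    expand.grid(sample_id = "blank1", replicate = 1:2,
                group = "blank", stringsAsFactors = FALSE)
  )
}

# Build an observation table from a per-feature intensity specification:
# `features` is a data.frame with columns mz, rt; `intensity` a matrix
# (features x injections) aligned with `design` rows. Zero = not observed.
obs_from_matrix <- function(features, intensity, design = tiny_design()) {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(design))) {
      if (intensity[i, j] <= 0) next
      rows[[length(rows) + 1L]] <- data.frame(
        mz = features$mz[i], rt = features$rt[i],
        intensity = intensity[i, j],
        sample_id = design$sample_id[j], replicate = design$replicate[j],
        group = design$group[j],
        source_id = sprintf("feat%d", i),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Intensity row helpers for the tiny design (12 case, 12... here 6 case,
# 6 control, 2 blank injections in tiny_design order: case columns first).
tiny_row <- function(case = rep(0, 6), control = rep(0, 6), blank = rep(0, 2)) {
  c(case, control, blank)
}

# A six-feature cascade fixture: each of the first five features fails
# exactly one filter; the sixth passes everything.
cascade_fixture <- function() {
  features <- data.frame(
    mz = c(298.9433, 348.9401, 398.9360, 500.3000, 448.9336, 498.9302),
    rt = c(5.0, 5.5, 0.5, 6.0, 6.5, 7.0)
  )
  good_case <- c(1600, 1650, 1550, 1580, 1620, 1600)
  quiet_ctrl <- rep(0, 6)
  intensity <- rbind(
    tiny_row(case = c(1600, 1650, 0, 1580, 1620, 1600)),         # fails RSD (absent once)
    tiny_row(case = good_case, blank = c(400, 420)),             # fails blank (x ~4)
    tiny_row(case = good_case),                                  # fails RT (0.5 min)
    tiny_row(case = good_case),                                  # fails KMD (hydrocarbon)
    tiny_row(case = good_case, control = c(1600, 1650, 1550, 1580, 1620, 1600)), # fails case-control
    tiny_row(case = good_case)                                   # survivor
  )
  list(obs = obs_from_matrix(features, intensity), features = features,
       intensity = intensity)
}

# Random well-formed observation table for property tests: a mixture of
# PFAS-like and hydrocarbon-like features with random group patterns.
random_obs_table <- function(n_features = 20) {
  design <- tiny_design()
  mz <- ifelse(stats::runif(n_features) < 0.5,
               298.9433 + cumsum(stats::runif(n_features, 1, 30)),
               300.2000 + cumsum(stats::runif(n_features, 1, 30)))
  features <- data.frame(mz = mz, rt = stats::runif(n_features, 0, 15))
  intensity <- matrix(0, n_features, nrow(design))
  for (i in seq_len(n_features)) {
    base <- stats::runif(1, 500, 5e5)
    present_case <- stats::runif(1) < 0.8
    present_ctrl <- stats::runif(1) < 0.5
    present_blank <- stats::runif(1) < 0.3
    jitter <- function(n, sd) exp(stats::rnorm(n, 0, sd))
    if (present_case) intensity[i, design$group == "case"] <-
        base * jitter(6, stats::runif(1, 0.02, 0.4))
    if (present_ctrl) intensity[i, design$group == "control"] <-
        base * stats::runif(1, 0.01, 1.2) * jitter(6, 0.1)
    if (present_blank) intensity[i, design$group == "blank"] <-
        base * stats::runif(1, 0.01, 0.3) * jitter(2, 0.1)
    # random dropouts
    drop <- stats::runif(nrow(design)) < 0.1
    intensity[i, drop] <- 0
  }
  # anchor: the first feature is present in every injection so that the
  # derived design always covers all groups
  intensity[1, ] <- stats::runif(nrow(design), 1e3, 1e4)
  obs_from_matrix(features, intensity, design)
}

# Independent re-application of the cascade, computed directly from the
# intensity matrix (no pipeline filter functions), for oracle comparison.
oracle_cascade <- function(x, cfg) {
  design <- x$design
  case_cols <- design$injection_id[design$group == "case"]
  blank_cols <- design$injection_id[design$group %in% cfg$blank_groups]
  m <- x$intensities
  pass <- logical(nrow(x$features))
  floor_value <- cfg$imputation_floor * min(m[m > 0])
  for (i in seq_len(nrow(x$features))) {
    ci <- m[i, case_cols]
    ok <- all(ci > 0) && (stats::sd(ci) / mean(ci) * 100 < cfg$rsd_max)
    bmax <- if (length(blank_cols)) max(m[i, blank_cols]) else 0
    ok <- ok && if (bmax == 0) mean(ci) > 0 else mean(ci) > cfg$blank_factor * bmax
    rt <- x$features$rt[i]
    ok <- ok && rt >= cfg$rt_window[1] && rt <= cfg$rt_window[2]
    kmd <- x$features$kmd[i]
    ok <- ok && kmd >= cfg$kmd_window[1] && kmd <= cfg$kmd_window[2]
    if (ok) {
      imp <- function(v) { v[v <= 0] <- floor_value; v }
      case_means <- sapply(unique(design$sample_id[design$group == "case"]),
        function(s) mean(imp(m[i, design$injection_id[design$sample_id == s]])))
      ctrl_means <- sapply(unique(design$sample_id[design$group == "control"]),
        function(s) mean(imp(m[i, design$injection_id[design$sample_id == s]])))
      lfc <- mean(log2(case_means)) - mean(log2(ctrl_means))
      p <- tryCatch(stats::t.test(log2(case_means), log2(ctrl_means))$p.value,
                    error = function(e) if (lfc == 0) 1 else 0)
      ok <- lfc > cfg$lfc_min && p < cfg$p_max
    }
    pass[i] <- ok
  }
  x$features$feature_id[pass]
}
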