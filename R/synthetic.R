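#' Default planted PFAS class specifications
#'
#' Homologous series templates for the PFAS classes observed in
#' AFFF-exposure screening of cattle blood and serum: perfluoroalkane
#' sulfonic acids (PFSA), carboxylic acids (PFCA), perfluoroalkane
#' sulfonamides (FASA), chlorinated sulfonic acids (Cl-PFSA),
#' sulfonamido-propanoic acids (FASA-PrA) and the N-methyl
#' sulfonamide-SO2 class (MeFASA-SO2). Each entry gives the neutral
#' formula template as a function of the perfluoroalkyl chain length, a
#' chromatographic RT model (RT grows with chain length, reversed-phase
#' convention), a case intensity scale, and the class fragment template
#' used to synthesize MS/MS spectra.
#'
#' @return Named list of class specs.
#' @export
default_class_specs <- function() {
  list(
    PFSA = list(
      chains = 4:8,
      formula = function(n) sprintf("C%dHF%dSO3", n, 2 * n + 1),
      ion_mode = "deprotonated",
      rt = function(n) 1.4 + 0.80 * n,
      case_median = 2e5,
      fragments = function(p) list(mz = c(ion_mz("SO3-"), ion_mz("FSO3-")),
                                   rel = c(100, 45))
    ),
    PFCA = list(
      chains = 8:11,
      formula = function(n) sprintf("C%dHF%dO2", n, 2 * n - 1),
      ion_mode = "deprotonated",
      rt = function(n) 0.9 + 0.72 * n,
      case_median = 1.2e5,
      fragments = function(p) list(mz = p - monoisotopic_mass("CO2"),
                                   rel = 100)
    ),
    FASA = list(
      chains = c(3, 4, 6, 8),
      formula = function(n) sprintf("C%dH2F%dNO2S", n, 2 * n + 1),
      ion_mode = "deprotonated",
      rt = function(n) 1.8 + 0.82 * n,
      case_median = 1.5e5,
      fragments = function(p) list(mz = ion_mz("NO2S-"), rel = 100)
    ),
    `Cl-PFSA` = list(
      chains = 6:8,
      formula = function(n) sprintf("C%dHClF%dSO3", n, 2 * n),
      ion_mode = "deprotonated",
      rt = function(n) 1.7 + 0.80 * n,
      case_median = 8e4,
      fragments = function(p) list(mz = c(ion_mz("SO3-"), ion_mz("FSO3-")),
                                   rel = c(100, 40))
    ),
    `FASA-PrA` = list(
      chains = c(6, 8),
      formula = function(n) sprintf("C%dH6F%dNO4S", n + 3, 2 * n + 1),
      ion_mode = "deprotonated",
      rt = function(n) 2.2 + 0.78 * n,
      case_median = 1e5,
      fragments = function(p) list(
        mz = c(p - monoisotopic_mass("C3H4O2"), ion_mz("NO2S-")),
        rel = c(100, 60))
    ),
    `MeFASA-SO2` = list(
      chains = c(6, 8),
      formula = function(n) sprintf("C%dH4F%dNO4S2", n + 1, 2 * n + 1),
      ion_mode = "deprotonated",
      rt = function(n) 2.0 + 0.76 * n,
      case_median = 9e4,
      fragments = function(p) list(
        mz = c(ion_mz("CH3NO2S-"), ion_mz("CH3NO4S2-"), ion_mz("NO2S-")),
        rel = c(100, 55, 40))
    )
  )
}

#' Synthetic dataset configuration
#'
#' Defaults mirror the study design the generator emulates: 4 case pools
#' and 4 control pools injected in triplicate with procedural blanks, a
#' 500-feature hydrogen-rich matrix background, and a mass-accuracy model
#' of 2 ppm Gaussian error truncated at 5 ppm (instrument calibration kept
#' below 2 ppm).
#'
#' @param n_case,n_control Number of case / control pooled samples.
#' @param n_replicates Replicate injections per sample.
#' @param n_blank Procedural blank injections.
#' @param n_matrix Number of matrix background features.
#' @param n_blank_features Number of blank-contamination features (present
#'   in blanks and samples at comparable intensity).
#' @param classes Planted class specs, see [default_class_specs()].
#' @param sigma_ppm Mass-error standard deviation (ppm).
#' @param max_ppm Mass-error truncation (ppm).
#' @param replicate_log_sd Natural-log SD of replicate intensity noise
#'   (0.1 gives ~10 % RSD).
#' @param feature_log_sd Natural-log SD of per-feature intensity medians
#'   around the class median.
#' @param control_contam_prob Probability that a planted PFAS appears in a
#'   control sample (at 1 % of its case level).
#' @param rt_jitter SD of per-observation RT noise (minutes).
#' @param matrix_median,matrix_log_sd Log-normal intensity model of the
#'   matrix background.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_case = 4, n_control = 4, n_replicates = 3,
                             n_blank = 3, n_matrix = 500,
                             n_blank_features = 30,
                             classes = default_class_specs(),
                             sigma_ppm = 2, max_ppm = 5,
                             replicate_log_sd = 0.10,
                             feature_log_sd = 0.5,
                             control_contam_prob = 0.02,
                             rt_jitter = 0.02,
                             matrix_median = 5e4, matrix_log_sd = 1.0) {
  if (n_replicates < 2) stop("need at least 2 replicate injections per sample")
  if (sigma_ppm <= 0 || max_ppm <= 0 || replicate_log_sd < 0)
    stop("invalid noise parameters")
  structure(as.list(environment()), class = "synthetic_config")
}

.trunc_norm <- function(n, sd, limit) {
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > limit)) x[bad] <- stats::rnorm(sum(bad), 0, sd)
  x
}

# One observation block for a single true feature across all injections.
# base: per-injection expected intensity (0 = absent); log-normal noise of
# SD log_sd is applied, m/z gets truncated-Gaussian ppm error, RT jitter.
.obs_block <- function(id, theo, rt, base, log_sd, design, cfg) {
  keep <- base > 0
  if (!any(keep)) return(NULL)
  n <- sum(keep)
  data.frame(
    mz = theo * (1 + .trunc_norm(n, cfg$sigma_ppm, cfg$max_ppm) * 1e-6),
    rt = rt + stats::rnorm(n, 0, cfg$rt_jitter),
    intensity = base[keep] * exp(stats::rnorm(n, 0, log_sd)),
    sample_id = design$sample_id[keep],
    replicate = design$replicate[keep],
    group = design$group[keep],
    source_id = id,
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic case-control screening dataset
#'
#' Produces a feature-observation table (one row per feature per injection
#' in which it was detected), replicate MS/MS spectra for the planted PFAS
#' features, and a ground-truth table. Planted PFAS appear in all case
#' injections with log-normal intensities and in controls only with a small
#' contamination probability; matrix features are hydrogen-rich compounds
#' (KMD outside the PFAS window with high probability) present in case and
#' control alike; blank-contamination features appear in blanks and samples
#' at comparable intensity. Observed m/z carries truncated-Gaussian ppm
#' error; RT increases with homologue chain length. Deterministic for a
#' fixed seed.
#'
#' @param cfg A [synthetic_config()].
#' @param seed Integer random seed.
#' @return List of class `synthetic_dataset` with elements `observations`
#'   (data frame as accepted by [align_observations()], with `source_id`
#'   carrying the truth id), `spectra` (named list truth_id -> list of
#'   `ms2_spectrum`), `truth` (data frame) and `cfg`.
#' @export
generate_dataset <- function(cfg = synthetic_config(), seed = 42) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  design <- rbind(
    expand.grid(sample_id = sprintf("case%d", seq_len(cfg$n_case)),
                replicate = seq_len(cfg$n_replicates), group = "case",
                stringsAsFactors = FALSE),
    expand.grid(sample_id = sprintf("ctrl%d", seq_len(cfg$n_control)),
                replicate = seq_len(cfg$n_replicates), group = "control",
                stringsAsFactors = FALSE),
    expand.grid(sample_id = "blank1", replicate = seq_len(cfg$n_blank),
                group = "blank", stringsAsFactors = FALSE)
  )

  truth <- list(); obs <- list(); spectra <- list()
  tid <- 0L

  ## planted PFAS homologous series
  for (cls in names(cfg$classes)) {
    spec <- cfg$classes[[cls]]
    for (n in spec$chains) {
      tid <- tid + 1L
      id <- sprintf("T%03d", tid)
      formula <- spec$formula(n)
      theo <- ion_mz(formula, mode = spec$ion_mode)
      rt <- spec$rt(n)
      feat_median <- spec$case_median * exp(stats::rnorm(1, 0, cfg$feature_log_sd))
      truth[[id]] <- data.frame(
        truth_id = id, type = "pfas", class_label = cls, chain_length = n,
        formula = formula, theoretical_mz = theo, rt = rt,
        case_median = feat_median, stringsAsFactors = FALSE)
      contam <- stats::runif(cfg$n_control) < cfg$control_contam_prob
      base <- numeric(nrow(design))
      is_case <- design$group == "case"
      is_ctrl <- design$group == "control"
      base[is_case] <- feat_median
      ctrl_idx <- as.integer(sub("ctrl", "", design$sample_id[is_ctrl]))
      base[is_ctrl] <- ifelse(contam[ctrl_idx], 0.01 * feat_median, 0)
      obs[[length(obs) + 1L]] <- .obs_block(id, theo, rt, base,
                                            cfg$replicate_log_sd, design, cfg)
      ## replicate DDA spectra from the class fragment template
      tmpl <- spec$fragments(theo)
      spectra[[id]] <- lapply(seq_len(cfg$n_replicates), function(k)
        ms2_spectrum(
          precursor_mz = theo * (1 + .trunc_norm(1, cfg$sigma_ppm, cfg$max_ppm) * 1e-6),
          mz = tmpl$mz + stats::rnorm(length(tmpl$mz), 0, 0.002),
          intensity = tmpl$rel * exp(stats::rnorm(length(tmpl$rel), 0, 0.1)),
          acquisition = "dda", collision_energy = 35))
    }
  }

  ## hydrogen-rich matrix background, present in case and control
  for (i in seq_len(cfg$n_matrix)) {
    tid <- tid + 1L
    id <- sprintf("T%03d", tid)
    c_n <- sample(14:40, 1)
    h_n <- max(1L, round(c_n * stats::runif(1, 1.3, 2.1)))
    o_n <- sample(0:10, 1)
    n_n <- sample(0:2, 1)
    formula <- paste0("C", c_n, "H", h_n,
                      if (n_n) paste0("N", n_n) else "",
                      if (o_n) paste0("O", o_n) else "")
    theo <- ion_mz(formula, mode = "deprotonated")
    rt <- stats::runif(1, 0.3, 20)
    feat_median <- cfg$matrix_median * exp(stats::rnorm(1, 0, cfg$matrix_log_sd))
    truth[[id]] <- data.frame(
      truth_id = id, type = "matrix", class_label = NA_character_,
      chain_length = NA_integer_, formula = formula, theoretical_mz = theo,
      rt = rt, case_median = feat_median, stringsAsFactors = FALSE)
    base <- ifelse(design$group == "blank", 0, feat_median)
    obs[[length(obs) + 1L]] <- .obs_block(id, theo, rt, base, 0.25, design, cfg)
  }

  ## blank contamination: present everywhere at comparable intensity
  for (i in seq_len(cfg$n_blank_features)) {
    tid <- tid + 1L
    id <- sprintf("T%03d", tid)
    c_n <- sample(10:30, 1)
    h_n <- max(1L, round(c_n * stats::runif(1, 1.4, 2.0)))
    o_n <- sample(1:8, 1)
    formula <- paste0("C", c_n, "H", h_n, "O", o_n)
    theo <- ion_mz(formula, mode = "deprotonated")
    rt <- stats::runif(1, 0.3, 20)
    feat_median <- 3e4 * exp(stats::rnorm(1, 0, 0.5))
    truth[[id]] <- data.frame(
      truth_id = id, type = "blank", class_label = NA_character_,
      chain_length = NA_integer_, formula = formula, theoretical_mz = theo,
      rt = rt, case_median = feat_median, stringsAsFactors = FALSE)
    base <- rep(feat_median, nrow(design))
    obs[[length(obs) + 1L]] <- .obs_block(id, theo, rt, base, 0.2, design, cfg)
  }

  structure(list(
    observations = do.call(rbind, obs),
    spectra = spectra,
    truth = do.call(rbind, truth),
    cfg = cfg
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$truth), " true features (",
      sum(x$truth$type == "pfas"), " planted PFAS), ",
      nrow(x$observations), " observations\n", sep = "")
  invisible(x)
}

#' Recovery metrics of the prioritization pipeline against ground truth
#'
#' Maps surviving features back to the ground truth through the propagated
#' `source_id` and computes recall over detectable planted PFAS features
#' (case median above `blank_factor` times their blank level -- zero for
#' planted features -- and RT inside the window) and precision (fraction of
#' survivors that are planted PFAS; NA when there are no survivors).
#'
#' @param prioritized An `nta_prioritized` object whose features carry
#'   `source_id`.
#' @param truth Truth table from [generate_dataset()].
#' @param cfg The [pipeline_config()] used (for the RT window).
#' @return List with `recall`, `precision`, `n_detectable`, `n_survivors`,
#'   `per_class` (data frame of per-class recall).
#' @export
evaluate_recovery <- function(prioritized, truth, cfg = pipeline_config()) {
  stopifnot(inherits(prioritized, "nta_prioritized"))
  feats <- prioritized$features
  surv <- feats$source_id[feats$feature_id %in% prioritized$survivors]
  surv <- surv[!is.na(surv)]
  if (length(surv) && !all(surv %in% truth$truth_id))
    stop("survivor source ids not found in truth table")
  pfas <- truth[truth$type == "pfas", ]
  detectable <- pfas$truth_id[
    pfas$case_median > 0 &
      pfas$rt >= cfg$rt_window[1] & pfas$rt <= cfg$rt_window[2]]
  recovered <- intersect(surv, detectable)
  n_surv <- sum(feats$feature_id %in% prioritized$survivors)
  per_class <- do.call(rbind, lapply(split(pfas, pfas$class_label), function(p) {
    det <- intersect(p$truth_id, detectable)
    data.frame(class_label = p$class_label[1], n_detectable = length(det),
               n_recovered = length(intersect(surv, det)),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  list(
    recall = if (length(detectable)) length(recovered) / length(detectable) else NA_real_,
    precision = if (n_surv) sum(surv %in% pfas$truth_id) / n_surv else NA_real_,
    n_detectable = length(detectable),
    n_survivors = n_surv,
    per_class = per_class
  )
}
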