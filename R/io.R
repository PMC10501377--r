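#' Read a feature-observation CSV
#'
#' Expected columns: `mz`, `rt_min`, `intensity`, `sample_id`, `replicate`,
#' `group` (and optionally `feature_id`, propagated as `source_id`).
#' Rows with non-numeric or invalid values are rejected with a warning that
#' lists their line numbers; a missing column is a schema error.
#'
#' @param path CSV file path (UTF-8, header required, decimal point).
#' @return Observation data frame as accepted by [align_observations()]
#'   (`rt_min` is returned as `rt`, in minutes).
#' @export
read_feature_observations <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("mz", "rt_min", "intensity", "sample_id", "replicate", "group")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("feature CSV ", sQuote(path), " lacks required column(s): ",
         paste(miss, collapse = ", "))
  mz <- suppressWarnings(as.numeric(raw$mz))
  rt <- suppressWarnings(as.numeric(raw$rt_min))
  intensity <- suppressWarnings(as.numeric(raw$intensity))
  replicate <- suppressWarnings(as.integer(raw$replicate))
  bad <- is.na(mz) | is.na(rt) | is.na(intensity) | is.na(replicate) |
    mz <= 0 | rt < 0 | intensity < 0 | !nzchar(raw$sample_id) |
    !nzchar(raw$group)
  if (any(bad)) {
    # +1 for the header line
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
  }
  out <- data.frame(
    mz = mz, rt = rt, intensity = intensity,
    sample_id = raw$sample_id, replicate = replicate, group = raw$group,
    stringsAsFactors = FALSE
  )
  if ("feature_id" %in% names(raw)) out$source_id <- raw$feature_id
  out[!bad, , drop = FALSE]
}

#' Write a feature-observation CSV
#'
#' Inverse of [read_feature_observations()]; writing then reading is the
#' identity on well-formed tables.
#'
#' @param obs Observation data frame (column `rt` in minutes).
#' @param path Output path.
#' @export
write_feature_observations <- function(obs, path) {
  out <- data.frame(
    feature_id = if ("source_id" %in% names(obs)) obs$source_id else NA,
    mz = obs$mz, rt_min = obs$rt, intensity = obs$intensity,
    sample_id = obs$sample_id, replicate = obs$replicate, group = obs$group
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read MS/MS spectra from an MGF file
#'
#' Parses Mascot Generic Format blocks (`BEGIN IONS` ... `END IONS`) with
#' `TITLE` carrying the feature id, `PEPMASS` the precursor m/z, and one
#' `m/z intensity` pair per line. Multiple blocks sharing a TITLE are
#' collected as replicate spectra. Peaks are sorted by m/z on read.
#'
#' @param path MGF file path.
#' @return Named list: feature id -> list of `ms2_spectrum`.
#' @export
read_spectra <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  i <- 1L; block <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      block <- block + 1L
      title <- NA_character_; pepmass <- NA_real_; ce <- NA_real_
      mzs <- numeric(0); ints <- numeric(0)
      closed <- FALSE
      i <- i + 1L
      while (i <= length(lines)) {
        l <- trimws(lines[i])
        if (l == "END IONS") { closed <- TRUE; break }
        if (l == "BEGIN IONS") break
        if (grepl("^TITLE=", l)) {
          title <- sub("^TITLE=", "", l)
        } else if (grepl("^PEPMASS=", l)) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "[ \t]")[[1]][1])
        } else if (grepl("^COLLISION_ENERGY=", l)) {
          ce <- as.numeric(sub("^COLLISION_ENERGY=", "", l))
        } else if (grepl("^[0-9]", l)) {
          xy <- as.numeric(strsplit(l, "[ \t]+")[[1]])
          mzs <- c(mzs, xy[1]); ints <- c(ints, xy[2])
        }
        i <- i + 1L
      }
      if (!closed)
        stop("MGF parse error in ", sQuote(path),
             ": block ", block, " has no END IONS")
      if (is.na(title)) title <- sprintf("block%d", block)
      sp <- ms2_spectrum(pepmass, mzs, ints, acquisition = "dda",
                         collision_energy = ce)
      out[[title]] <- c(out[[title]], list(sp))
    } else if (line == "END IONS") {
      stop("MGF parse error in ", sQuote(path),
           ": END IONS without matching BEGIN (after block ", block, ")")
    }
    i <- i + 1L
  }
  out
}

#' Write spectra to an MGF file
#'
#' @param spectra Named list: feature id -> list of `ms2_spectrum` (or a
#'   single spectrum).
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(spectra)) {
    sps <- spectra[[id]]
    if (inherits(sps, "ms2_spectrum")) sps <- list(sps)
    for (sp in sps) {
      writeLines("BEGIN IONS", con)
      writeLines(paste0("TITLE=", id), con)
      writeLines(sprintf("PEPMASS=%.6f", sp$precursor_mz), con)
      writeLines("CHARGE=1-", con)
      if (!is.na(sp$collision_energy))
        writeLines(sprintf("COLLISION_ENERGY=%g", sp$collision_energy), con)
      writeLines(sprintf("%.6f %.4f", sp$mz, sp$intensity), con)
      writeLines(c("END IONS", ""), con)
    }
  }
  invisible(path)
}

#' Read a suspect list CSV
#'
#' Columns: `name`, `formula`, `ion_mode` (`ion` or `deprotonated`),
#' optionally `class_label` and `source`.
#'
#' @param path CSV file path.
#' @return Data frame as accepted by [suspect_screen()].
#' @export
read_suspects <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "ion_mode")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("suspect CSV lacks required column(s): ", paste(miss, collapse = ", "))
  bad_mode <- !tab$ion_mode %in% c("ion", "deprotonated")
  if (any(bad_mode))
    stop("invalid ion_mode value(s): ",
         paste(unique(tab$ion_mode[bad_mode]), collapse = ", "))
  tab
}

#' Write / read a run configuration (plain-text YAML)
#'
#' @param cfg A list (e.g. combining [pipeline_config()] fields, annotation
#'   criteria, paths and a seed).
#' @param path YAML file path.
#' @return `read_run_config` returns the list; pipeline fields are restored
#'   as a `pipeline_config`.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  pipe_fields <- names(formals(pipeline_config))
  have <- intersect(pipe_fields, names(cfg))
  if (length(have)) cfg[have] <- do.call(pipeline_config, cfg[have])[have]
  cfg
}

# Small stable content hash (FNV-1a over the serialized text) used for the
# provenance block; not cryptographic.
.config_hash <- function(x) {
  txt <- paste(utils::capture.output(utils::str(x)), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to keep doubles exact
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- ((h1 * 16777619) %% 65536 * 65536 + h0 * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
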