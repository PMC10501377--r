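#' Parse a Hill-style molecular formula
#'
#' Parses strings such as `"C9H5F13NO4S"` into an element-count structure.
#' An optional trailing `"-"` or `"+"` marks a singly charged anion/cation
#' (the negative-mode workflows here only use `"-"`). Element symbols are
#' case sensitive; counts default to 1.
#'
#' @param text Formula string, e.g. `"C6HF13SO4"` or `"C9H5F13NO4S-"`.
#' @return An object of class `formula_counts`: a list with `counts`
#'   (named integer vector, element -> count) and `charge` (integer).
#' @examples
#' parse_formula("C9H5F13NO4S-")
#' parse_formula("H2O")
#' @seealso [format_formula()], [monoisotopic_mass()], [ion_mz()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula string must be a single non-empty character value")
  charge <- 0L
  body <- text
  last <- substr(body, nchar(body), nchar(body))
  if (last == "-") {
    charge <- -1L
    body <- substr(body, 1L, nchar(body) - 1L)
  } else if (last == "+") {
    charge <- 1L
    body <- substr(body, 1L, nchar(body) - 1L)
  }
  if (!nzchar(body)) stop("formula string has no elemental composition")
  matched <- regmatches(body, gregexpr("([A-Z][a-z]?)([0-9]*)", body, perl = TRUE))[[1]]
  if (sum(nchar(matched)) != nchar(body))
    stop("could not parse formula string: ", sQuote(text))
  known <- element_table()$element
  counts <- integer(0)
  for (tok in matched) {
    sym <- sub("[0-9]+$", "", tok)
    n <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (!sym %in% known)
      stop("unknown element symbol ", sQuote(sym), " in formula ", sQuote(text))
    counts[sym] <- (if (sym %in% names(counts)) counts[[sym]] else 0L) + n
  }
  new_formula(counts, charge)
}

#' Construct a formula from element counts
#'
#' @param counts Named integer vector of element counts (all >= 0, at least
#'   one > 0), names drawn from [element_table()].
#' @param charge Integer charge (0 for neutral, -1 for the anions used in
#'   negative-mode screening).
#' @return A `formula_counts` object.
#' @export
new_formula <- function(counts, charge = 0L) {
  counts <- counts[counts != 0L]
  if (length(counts) == 0L) stop("formula must contain at least one atom")
  if (any(counts < 0L)) stop("element counts must be non-negative")
  known <- element_table()$element
  bad <- setdiff(names(counts), known)
  if (length(bad)) stop("unknown element symbol ", sQuote(bad[1]))
  # Hill order: C, then H, then other elements alphabetically
  ord <- names(counts)
  hill <- c(intersect(c("C", "H"), ord), sort(setdiff(ord, c("C", "H"))))
  structure(
    list(counts = counts[hill], charge = as.integer(charge)),
    class = "formula_counts"
  )
}

#' Format a formula back to its Hill-style string
#'
#' Inverse of [parse_formula()]: `parse_formula(format_formula(f))` returns
#' `f` for any supported formula.
#'
#' @param f A `formula_counts` object.
#' @return Character scalar.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "formula_counts"))
  parts <- vapply(seq_along(f$counts), function(i) {
    n <- f$counts[[i]]
    paste0(names(f$counts)[i], if (n > 1L) n else "")
  }, character(1))
  suffix <- if (f$charge < 0) "-" else if (f$charge > 0) "+" else ""
  paste0(paste(parts, collapse = ""), suffix)
}

#' @export
print.formula_counts <- function(x, ...) {
  cat("<formula>", format_formula(x))
  if (x$charge != 0) cat(" (charge ", x$charge, ")", sep = "")
  cat("  monoisotopic mass:", sprintf("%.6f", monoisotopic_mass(x)), "Da\n")
  invisible(x)
}

.as_formula <- function(f) {
  if (inherits(f, "formula_counts")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' Sum of the most-abundant-isotope atomic masses of all atoms. Electron
#' mass is *not* included here (see [ion_mz()] for ions).
#'
#' @param f A `formula_counts` object or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("CF2")     # 49.996806
#' monoisotopic_mass("C3H4O2")  # 72.021129, the propionate-group loss
#' @export
monoisotopic_mass <- function(f) {
  f <- .as_formula(f)
  masses <- .element_masses()
  sum(masses[names(f$counts)] * f$counts)
}

#' Theoretical m/z of a singly charged negative ion
#'
#' Two conventions are supported. `mode = "ion"` treats the formula as the
#' ion composition as written (e.g. `C9H5F13NO4S-`) and adds one electron
#' mass per negative charge. `mode = "deprotonated"` treats the formula as
#' the neutral molecule and computes the \[M-H\]- mass (subtract one H atom,
#' add one electron). Electron mass (0.000549 Da) is always included.
#'
#' @param f Formula (object or string). For `mode = "ion"` a trailing `-`
#'   is accepted and implies charge -1.
#' @param mode `"ion"` or `"deprotonated"`.
#' @return m/z in Da.
#' @examples
#' ion_mz("C9H5F13NO4S-", mode = "ion")     # 469.9737
#' ion_mz("C6HF13SO4", mode = "deprotonated") # 414.9315
#' @export
ion_mz <- function(f, mode = c("ion", "deprotonated")) {
  mode <- match.arg(mode)
  f <- .as_formula(f)
  if (mode == "ion") {
    charge <- if (f$charge == 0L) -1L else f$charge
    if (charge != -1L) stop("only singly charged negative ions are supported")
    monoisotopic_mass(f) + ELECTRON_MASS
  } else {
    h <- if ("H" %in% names(f$counts)) f$counts[["H"]] else 0L
    if (h < 1L) stop("cannot deprotonate a formula with no hydrogen: ",
                     format_formula(f))
    monoisotopic_mass(f) - .element_masses()[["H"]] + ELECTRON_MASS
  }
}

#' Signed mass error in parts per million
#'
#' @param observed Observed m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return `(observed - theoretical) / theoretical * 1e6`.
#' @examples
#' ppm_error(469.9736, 469.9737)
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Ring-and-double-bond equivalents
#'
#' RDB = C - (H + F + Cl)/2 + (N + P)/2 + 1 over the supported elements.
#' Half-integral results indicate a radical or an ionic composition; they
#' are returned as-is with attribute `ionic = TRUE` rather than an error,
#' since RDB is used only as a candidate plausibility screen.
#'
#' @param f Formula (object or string), normally a neutral composition.
#' @return Numeric RDB value, possibly half-integral.
#' @examples
#' rdb("C9H6F13NO4S") # 1
#' rdb("C6H6")        # 4
#' @export
rdb <- function(f) {
  f <- .as_formula(f)
  cnt <- function(e) if (e %in% names(f$counts)) f$counts[[e]] else 0L
  val <- cnt("C") - (cnt("H") + cnt("F") + cnt("Cl")) / 2 +
    (cnt("N") + cnt("P")) / 2 + 1
  attr(val, "ionic") <- (val %% 1) != 0
  val
}

#' Predicted first-isotope (M+1)/M intensity ratio
#'
#' Single-heavy-isotope substitution model: the M+1 peak collects all
#' molecules carrying exactly one 13C, 2H, 15N, 17O or 33S, so the
#' (M+1)/M ratio is `sum over elements of count * abundance ratio`.
#'
#' @param f Formula (object or string).
#' @return Ratio (fraction, not percent).
#' @examples
#' isotope_m1_ratio("C")    # ~0.0108, the 13C/12C abundance ratio
#' isotope_m1_ratio("F13")  # 0: fluorine is monoisotopic
#' @export
isotope_m1_ratio <- function(f) {
  f <- .as_formula(f)
  m1 <- .element_m1()
  sum(m1[names(f$counts)] * f$counts)
}

# Exact CF2 mass, the Kendrick base unit for PFAS homologue analysis.
#' Exact mass of the CF2 repeat unit
#' @return 49.996806 Da (to table precision).
#' @export
cf2_mass <- function() monoisotopic_mass("CF2")

#' CF2-normalized Kendrick mass values
#'
#' Rescales m/z so that the CF2 repeat unit has integer mass 50:
#' `KM = mz * 50 / 49.996806`; the nominal Kendrick mass is the nearest
#' integer and the Kendrick mass defect is `KMD = round(KM) - KM`.
#' Members of a CF2 homologous series share a KMD, and PFAS generally fall
#' in the window -0.15..0.15 while hydrogen-rich matrix compounds fall
#' outside it.
#'
#' @param mz Numeric vector of m/z values (> 0).
#' @param unit_mass Exact mass of the repeat unit (default CF2).
#' @param unit_nominal Nominal (integer) mass of the repeat unit (default 50).
#' @return A data frame of class `kendrick_values` with columns `mz`,
#'   `kendrick_mass`, `nominal_kendrick_mass`, `kmd`.
#' @examples
#' kendrick(c(469.9736, 500.3000))
#' @export
kendrick <- function(mz, unit_mass = cf2_mass(), unit_nominal = 50) {
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("m/z values must be positive")
  km <- mz * unit_nominal / unit_mass
  nkm <- round(km)
  out <- data.frame(
    mz = mz,
    kendrick_mass = km,
    nominal_kendrick_mass = as.integer(nkm),
    kmd = nkm - km
  )
  class(out) <- c("kendrick_values", "data.frame")
  out
}
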