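#' Element constants used for exact-mass arithmetic
#'
#' Monoisotopic (most abundant isotope) atomic masses and the M+1
#' single-substitution abundance ratio for every element supported by the
#' formula arithmetic in this package. Masses are IUPAC/AME values, pinned
#' here to keep all computations reproducible; they are quoted to >= 6
#' decimal places. The M+1 ratio for an element is
#' abundance(M+1 isotope) / abundance(principal isotope), e.g. 13C/12C;
#' elements whose next isotope is M+2 (Cl, Br-like) or negligible carry 0.
#'
#' @return A data frame with columns `element`, `mass` (Da) and
#'   `m1_ratio` (dimensionless).
#' @examples
#' element_table()
#' @export
element_table <- function() {
  data.frame(
    element = c("C", "H", "N", "O", "S", "F", "Cl", "P", "Na", "K"),
    mass = c(
      12.000000000,
      1.007825032,
      14.003074005,
      15.994914620,
      31.972071174,
      18.998403163,
      34.968852682,
      30.973761998,
      22.989769282,
      38.963706486
    ),
    m1_ratio = c(
      0.0107 / 0.9893,    # 13C / 12C
      0.000115 / 0.999885, # 2H / 1H
      0.00364 / 0.99636,   # 15N / 14N
      0.00038 / 0.99757,   # 17O / 16O
      0.0075 / 0.9499,     # 33S / 32S
      0, # F monoisotopic
      0, # 35Cl -> 37Cl is M+2
      0, # P monoisotopic
      0, # Na monoisotopic
      0.000117 / 0.932581  # 40K / 39K
    ),
    stringsAsFactors = FALSE
  )
}

# Mass of the electron (Da); one per negative charge is added to ion m/z.
ELECTRON_MASS <- 0.000548580

.element_masses <- function() {
  tab <- element_table()
  stats::setNames(tab$mass, tab$element)
}

.element_m1 <- function() {
  tab <- element_table()
  stats::setNames(tab$m1_ratio, tab$element)
}
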