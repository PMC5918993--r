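# Element property tables: atomic masses (Da) and van der Waals radii (A).
# Radii follow Bondi's compilation for the common biomolecular elements;
# both tables are overridable per call (see lookup_mass / lookup_radius).

.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  "NA" = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  MN = 54.938, FE = 55.845, CU = 63.546
)

.element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  "NA" = 2.27, K = 2.75, MG = 1.73, CA = 2.31, ZN = 1.39,
  MN = 1.61, FE = 1.56, CU = 1.40
)

.norm_element <- function(x) toupper(trimws(x))

# Element symbol inferred from a PDB atom name when the element column is
# blank: strip digits/primes, try the two-letter prefix first (ions such as
# MG, CL), then the first letter.
.element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", .norm_element(name))
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    two <- substr(nm[i], 1, 2)
    one <- substr(nm[i], 1, 1)
    if (nchar(nm[i]) >= 2 && two %in% names(.element_radii) &&
        two %in% c("MG", "CL", "BR", "NA", "ZN", "MN", "FE", "CU", "CA")) {
      # two-letter match only for known ion/metal symbols; "CA" as an atom
      # name is almost always an alpha-carbon, so prefer C for ATOM records
      out[i] <- two
    } else if (one %in% names(.element_radii)) {
      out[i] <- one
    } else {
      out[i] <- NA_character_
    }
  }
  out
}

#' Look up atomic masses or van der Waals radii
#'
#' Values are keyed by element symbol, with a per-atom-name override table
#' taking precedence. Unknown elements raise a lookup error.
#'
#' @param element character vector of element symbols.
#' @param name optional character vector of atom names (same length), used
#'   for the override table.
#' @param override named numeric vector keyed by atom name, or `NULL`.
#' @param table the default lookup table (named numeric, keyed by element).
#' @return numeric vector of values.
#' @keywords internal
.lookup_property <- function(element, name = NULL, override = NULL, table) {
  el <- .norm_element(element)
  out <- unname(table[el])
  if (!is.null(override) && !is.null(name)) {
    hit <- match(.norm_element(name), .norm_element(names(override)))
    out[!is.na(hit)] <- unname(override)[hit[!is.na(hit)]]
  }
  if (anyNA(out)) {
    bad <- unique(el[is.na(out)])
    stop("trajkit lookup error: no value for element(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

lookup_mass <- function(element, name = NULL, override = NULL)
  .lookup_property(element, name, override, .element_masses)

lookup_radius <- function(element, name = NULL, override = NULL)
  .lookup_property(element, name, override, .element_radii)
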