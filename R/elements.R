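# Element tables for density simulation and bond inference.

.ELEMENT_Z <- c(
  H = 1, D = 1, C = 6, N = 7, O = 8, F = 9, `NA` = 11, MG = 12, SI = 14,
  P = 15, S = 16, CL = 17, K = 19, CA = 20, MN = 25, FE = 26, CO = 27,
  NI = 28, CU = 29, ZN = 30, SE = 34, BR = 35, I = 53
)

# single-bond covalent radii (Angstrom), used for distance-based bond inference
.COVALENT_R <- c(
  H = 0.37, D = 0.37, C = 0.77, N = 0.75, O = 0.73, F = 0.71, P = 1.06,
  S = 1.02, CL = 0.99, BR = 1.14, I = 1.33, SE = 1.17, SI = 1.11,
  FE = 1.25, ZN = 1.22, MG = 1.30, MN = 1.35, `NA` = 1.54, K = 1.96,
  CA = 1.74, CO = 1.26, NI = 1.21, CU = 1.38
)

# Two-letter symbols accepted during atom-name fallback. Deliberately excludes
# names that collide with protein atom naming (CA, CD, NA, ...): those resolve
# to their first letter unless the element column says otherwise.
.TWO_LETTER_SAFE <- c("CL", "BR", "FE", "ZN", "SE", "MN", "SI", "MG")

#' Infer chemical elements from atom names
#'
#' Fallback used when a coordinate file lacks (or has unrecognized) element
#' columns: the leading alphabetic characters of the atom name are matched
#' against a fixed table. Two-letter matches are only accepted for symbols
#' that cannot be confused with standard protein atom names (so "CA" is
#' carbon-alpha, never calcium).
#'
#' @param atom_names character vector of atom names (e.g. "CA", "CL1", "O2'").
#' @return character vector of upper-case element symbols; unrecognized names
#'   yield `NA`.
#' @export
guess_element <- function(atom_names) {
  alpha <- toupper(gsub("[^A-Za-z].*$", "", sub("^[^A-Za-z]*", "", atom_names)))
  two <- substr(alpha, 1L, 2L)
  one <- substr(alpha, 1L, 1L)
  out <- ifelse(two %in% .TWO_LETTER_SAFE, two,
                ifelse(one %in% names(.ELEMENT_Z), one, NA_character_))
  out[!nzchar(alpha)] <- NA_character_
  out
}

element_z <- function(elements) {
  z <- .ELEMENT_Z[toupper(elements)]
  if (anyNA(z))
    stop("unrecognized element(s): ",
         paste(unique(elements[is.na(z)]), collapse = ", "))
  unname(z)
}

covalent_radius <- function(elements) {
  r <- .COVALENT_R[toupper(elements)]
  r[is.na(r)] <- 0.77  # treat unknowns as carbon-like
  unname(r)
}
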