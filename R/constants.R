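#' Physical constants used throughout the package
#'
#' CODATA 2018 values, pinned in one place so every calculator agrees.
#'
#' @format A named list with elements:
#' \describe{
#'   \item{R}{Molar gas constant, J mol^-1 K^-1.}
#'   \item{kB}{Boltzmann constant, J K^-1.}
#'   \item{N_A}{Avogadro constant, mol^-1.}
#'   \item{eps64}{Relative machine precision of IEEE 64-bit floats, 2^-53 --
#'     the smallest relative increment by which a global simulation time can
#'     advance, and the reason chunked time accumulation exists.}
#' }
#' @export
crn_constants <- list(
  R     = 8.314462618,
  kB    = 1.380649e-23,
  N_A   = 6.02214076e23,
  eps64 = 2^-53
)

#' Covalent radii table for bond perception
#'
#' Single-bond covalent radii (Angstrom) with a dimensionless scaling
#' `alpha`: two atoms i, j are perceived as bonded when their distance is
#' below `alpha * (R_i + R_j)`.  The hydrogen radius is 0.37 A so that H2
#' (bond length 0.74 A) is perceived as bonded at the default `alpha = 1.1`.
#'
#' @param radii named numeric vector of per-element radii (Angstrom) used to
#'   override or extend the shipped defaults.
#' @param alpha cutoff scaling parameter (default 1.1).
#' @return An object of class `crn_radii`: list with `radius_by_element`
#'   (named numeric) and `alpha`.
#' @examples
#' tab <- covalent_radii()
#' tab$radius_by_element[["C"]]
#' @export
covalent_radii <- function(radii = NULL, alpha = 1.1) {
  default <- c(
    H = 0.37, He = 0.32,
    B = 0.85, C = 0.77, N = 0.75, O = 0.73, F = 0.71,
    Si = 1.11, P = 1.06, S = 1.02, Cl = 0.99, Br = 1.14, I = 1.33
  )
  if (!is.null(radii)) {
    if (is.null(names(radii)) || any(!nzchar(names(radii)))) {
      stop("`radii` must be a named numeric vector", call. = FALSE)
    }
    default[names(radii)] <- radii
  }
  if (any(default <= 0)) stop("all covalent radii must be positive", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("`alpha` must be a single positive number", call. = FALSE)
  }
  structure(
    list(radius_by_element = default, alpha = alpha),
    class = "crn_radii"
  )
}

#' Default valence limits used by move validation and SMILES hydrogen folding
#'
#' @param limits named integer vector overriding defaults (C 4, H 1, O 2,
#'   N 3, plus a few common elements).
#' @return An object of class `crn_valence`: named integer vector of maximum
#'   degrees per element.
#' @export
valence_constraints <- function(limits = NULL) {
  default <- c(H = 1L, He = 0L, C = 4L, N = 3L, O = 2L, F = 1L,
               Si = 4L, P = 3L, S = 2L, Cl = 1L, Br = 1L, I = 1L, B = 3L)
  if (!is.null(limits)) {
    if (is.null(names(limits))) stop("`limits` must be named", call. = FALSE)
    default[names(limits)] <- as.integer(limits)
  }
  if (any(default < 0)) stop("valence limits must be >= 0", call. = FALSE)
  structure(default, class = "crn_valence")
}
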