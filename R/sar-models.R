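#' Extinction fraction under the classic species-area relationship
#'
#' The classic power-law SAR, \eqn{S(A) \sim A^z}, predicts that converting an
#' area \eqn{a} of a landscape of native habitat of total area \eqn{A} drives
#' extinct the fraction
#' \deqn{\varepsilon(a) = 1 - \left(\frac{A - a}{A}\right)^z.}
#' The converted habitat is assumed completely hostile: when everything is
#' converted (\eqn{a = A}) every species is lost.
#'
#' @param a Converted (human-modified) area. Vectorised; any consistent area
#'   unit, \code{0 <= a <= A}.
#' @param A Total landscape area, \code{> 0}.
#' @param z SAR exponent, \code{> 0}. Typical short-term values are around
#'   0.2; \code{z = 1} gives proportional loss.
#' @return Extinction fraction(s) in \code{[0, 1]}.
#' @seealso [countryside_extinction()] for the matrix-tolerant variant,
#'   [linear_extinction()] for the plot-scale linear model.
#' @examples
#' classic_extinction(0.9, 1, 0.2) # ~0.37: 90% loss kills only ~37% of species
#' @export
classic_extinction <- function(a, A, z) {
  check_areas(a, A)
  if (any(z <= 0)) {
    stop("`z` must be positive", call. = FALSE)
  }
  1 - ((A - a) / A)^z
}

#' Species richness under the countryside species-area relationship
#'
#' The countryside SAR generalises the power-law SAR to landscapes with
#' several habitat types: the richness of a species group is
#' \deqn{S(A_1, \ldots, A_n) = c \left(\sum_j h_j A_j\right)^z,}
#' where each habitat's area \eqn{A_j} is weighted by the group's affinity
#' \eqn{h_j} for that habitat. Native habitat conventionally has
#' \eqn{h_1 = 1}; a fully hostile habitat has \eqn{h_j = 0}.
#'
#' @param areas Numeric vector of per-habitat areas (all \code{>= 0}, summing
#'   to \code{> 0}), in the same order as \code{affinities}.
#' @param affinities Numeric vector of per-habitat affinities (all
#'   \code{>= 0}); values above 1 are allowed and correspond to a habitat
#'   richer than native.
#' @param z SAR exponent, \code{> 0}.
#' @param c Relative local abundance scaling of the species group,
#'   \code{> 0}. Cancels in every extinction fraction; kept for the full
#'   richness form.
#' @return Species richness (same units as \code{c}).
#' @examples
#' countryside_richness(c(1, 0), c(1, 0.01), z = 0.2) # pristine unit landscape
#' @export
countryside_richness <- function(areas, affinities, z, c = 1) {
  if (length(areas) != length(affinities)) {
    stop("`areas` and `affinities` must have the same length", call. = FALSE)
  }
  if (any(areas < 0)) stop("`areas` must be non-negative", call. = FALSE)
  if (sum(areas) <= 0) stop("`areas` must have a positive total", call. = FALSE)
  if (any(affinities < 0)) stop("`affinities` must be non-negative", call. = FALSE)
  if (z <= 0) stop("`z` must be positive", call. = FALSE)
  if (c <= 0) stop("`c` must be positive", call. = FALSE)
  c * sum(affinities * areas)^z
}

#' Extinction fraction under the two-habitat countryside SAR
#'
#' For a landscape of native habitat (affinity \code{h1}) of which an area
#' \eqn{a} is converted to a modified habitat (affinity \code{h2}), the
#' countryside SAR predicts the extinction fraction
#' \deqn{\varepsilon(a) = 1 - \left(\frac{h_1 (A - a) + h_2 a}{h_1 A}\right)^z.}
#' Whenever \eqn{h_2 > 0} some species persist even under full conversion:
#' \eqn{\varepsilon(A) = 1 - (h_2/h_1)^z < 1}. With \eqn{h_2 = 0} the classic
#' SAR is recovered exactly. If \eqn{h_2 > h_1} the result is negative (a
#' richness gain); callers must tolerate signed values — they are not
#' clamped, so that window averages stay unbiased.
#'
#' @inheritParams classic_extinction
#' @param h1 Affinity for the native habitat, \code{> 0} (conventionally 1).
#' @param h2 Affinity for the modified habitat, \code{>= 0}.
#' @return Extinction fraction(s), possibly negative when \code{h2 > h1}.
#' @examples
#' countryside_extinction(0.9, 1, h1 = 1, h2 = 0.01, z = 0.2) # ~0.358
#' @export
countryside_extinction <- function(a, A, h1 = 1, h2, z) {
  check_areas(a, A)
  if (any(h1 <= 0)) stop("`h1` must be positive", call. = FALSE)
  if (any(h2 < 0)) stop("`h2` must be non-negative", call. = FALSE)
  if (any(z <= 0)) stop("`z` must be positive", call. = FALSE)
  1 - ((h1 * (A - a) + h2 * a) / (h1 * A))^z
}

#' Extinction fraction under the linear (plot-scale) model
#'
#' Assumes the fraction of species lost is directly proportional to the
#' converted fraction times the plot-scale sensitivity:
#' \eqn{\varepsilon(a) = a \sigma / A}. This is the countryside SAR with
#' \code{z = 1} and \code{h2 = 1 - sigma}, and is how plot-scale field
#' results are (incorrectly) extrapolated linearly to larger areas.
#'
#' @inheritParams classic_extinction
#' @param sigma Plot-scale sensitivity \eqn{\sigma \le 1}; may be negative
#'   (modified habitat richer than native).
#' @return Extinction fraction(s); negative when \code{sigma < 0}.
#' @examples
#' linear_extinction(0.9, 1, sigma = 0.6) # 0.54
#' @export
linear_extinction <- function(a, A, sigma) {
  check_areas(a, A)
  if (any(sigma > 1)) stop("`sigma` must be <= 1", call. = FALSE)
  a * sigma / A
}

#' Plot-scale sensitivity from a native/modified richness pair
#'
#' \eqn{\sigma = 1 - S_{modified} / S_{native}}: the proportion of plot-scale
#' species richness lost on full conversion of native habitat. Zero for a
#' fully hospitable modified habitat, one for a fully hostile one, and
#' negative when the modified habitat holds more species than the native.
#'
#' @param s_native Species richness in native habitat, \code{> 0}. Vectorised.
#' @param s_modified Species richness in the modified habitat, \code{>= 0}.
#' @return Sensitivity value(s) \code{<= 1}.
#' @examples
#' sensitivity_from_richness(10, 4)  # 0.6
#' sensitivity_from_richness(10, 13) # -0.3, richness gain
#' @export
sensitivity_from_richness <- function(s_native, s_modified) {
  if (any(s_native <= 0)) {
    stop("sensitivity undefined: `s_native` must be positive", call. = FALSE)
  }
  if (any(s_modified < 0)) {
    stop("`s_modified` must be non-negative", call. = FALSE)
  }
  1 - s_modified / s_native
}

#' Convert a plot-scale sensitivity into a countryside-SAR affinity
#'
#' Sensitivities and affinities are two views of the same quantity: the
#' extinction fraction under full conversion is \eqn{\sigma = 1 - (h/h_1)^z}
#' with \eqn{h_1 = 1}, so \deqn{h = (1 - \sigma)^{1/z}.}
#' A sensitivity of 0.6 at \code{z = 0.2} gives \eqn{h = 0.4^5 = 0.01024},
#' the affinity of permanent cropland used in the scaling experiments.
#'
#' @param sigma Sensitivity, \code{<= 1}; negative values give \code{h > 1}.
#' @param z SAR exponent, \code{> 0}.
#' @return Affinity \code{h >= 0}.
#' @seealso [sensitivity_from_affinity()] for the inverse.
#' @export
affinity_from_sensitivity <- function(sigma, z) {
  if (any(sigma > 1)) stop("`sigma` must be <= 1", call. = FALSE)
  if (any(z <= 0)) stop("`z` must be positive", call. = FALSE)
  (1 - sigma)^(1 / z)
}

#' Convert a countryside-SAR affinity into a plot-scale sensitivity
#'
#' Algebraic inverse of [affinity_from_sensitivity()]: \eqn{\sigma = 1 - h^z}.
#'
#' @param h Affinity, \code{>= 0}.
#' @param z SAR exponent, \code{> 0}.
#' @return Sensitivity \code{<= 1}.
#' @export
sensitivity_from_affinity <- function(h, z) {
  if (any(h < 0)) stop("`h` must be non-negative", call. = FALSE)
  if (any(z <= 0)) stop("`z` must be positive", call. = FALSE)
  1 - h^z
}

# shared domain checks for the converted/total area pair
check_areas <- function(a, A) {
  if (any(A <= 0)) stop("`A` must be positive", call. = FALSE)
  if (any(a < 0)) stop("`a` must be non-negative", call. = FALSE)
  if (any(a > A)) stop("`a` must not exceed `A`", call. = FALSE)
  invisible(TRUE)
}
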