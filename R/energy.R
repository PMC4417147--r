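#' Conformational energy of a chain
#'
#' The conformational energy of a chromatin chain is the sum of three
#' terms, all in units of `kBT`:
#' \describe{
#'   \item{stretching}{harmonic bonds,
#'     \eqn{\sum_i \frac{1}{2} k_s (l_i - l_{i0})^2}, penalizing deviation
#'     of each segment length from its rest length;}
#'   \item{bending}{worm-like-chain bending,
#'     \eqn{\sum_i \frac{1}{2} k_\theta \theta_i^2}, where \eqn{\theta_i}
#'     is the planar angle between consecutive bond vectors;}
#'   \item{excluded volume}{a purely repulsive truncated-and-shifted
#'     Lennard-Jones (WCA) potential
#'     \eqn{4\epsilon[(\delta/d)^{12} - (\delta/d)^6 + 1/4]} over all
#'     end-point pairs closer than \eqn{2^{1/6}\delta}.}
#' }
#' A coincident counted pair makes the excluded-volume term `+Inf`, which
#' the optimizer treats as a rejected state.
#'
#' @param coords conformation matrix, `(n + 1) x 3`.
#' @param model a [segment_model()] (needed for rest lengths).
#' @param params an [energy_params()] object.
#' @return Scalar energy in `kBT` units (`total_energy`), or the named
#'   component.
#' @examples
#' m <- segment_model(cbind(c(0, 3900), c(3900, 7800)))
#' x <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
#' total_energy(x, m)  # straight chain at rest length, beads beyond cutoff
#' @export
total_energy <- function(coords, model, params = energy_params()) {
  e <- energy_components(coords, model, params)
  e$stretch + e$bend + e$exclude
}

#' @rdname total_energy
#' @export
energy_components <- function(coords, model, params = energy_params()) {
  coords <- as_conformation(coords, model)
  e <- energy_terms_cpp(coords, model$rest_lengths, params$k_s,
                        params$k_theta, params$epsilon, params$delta)
  if (is.na(e$bend))
    stop("degenerate geometry: zero-length bond makes a bend angle undefined")
  e
}

#' @rdname total_energy
#' @export
stretch_energy <- function(coords, model, params = energy_params()) {
  energy_components(coords, model, params)$stretch
}

#' Bending energy of a chain
#'
#' @inheritParams total_energy
#' @return Scalar bending energy in `kBT`.
#' @export
bend_energy <- function(coords, params = energy_params()) {
  coords <- as_conformation(coords)
  e <- energy_terms_cpp(coords, rep(1, nrow(coords) - 1L), params$k_s,
                        params$k_theta, params$epsilon, params$delta)
  if (is.na(e$bend))
    stop("degenerate geometry: zero-length bond makes a bend angle undefined")
  e$bend
}

#' Excluded-volume (WCA) energy of a point set
#'
#' @inheritParams total_energy
#' @return Scalar excluded-volume energy in `kBT`; `+Inf` if any counted
#'   pair coincides.
#' @export
exclude_energy <- function(coords, params = energy_params()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coordinates must have 3 columns")
  energy_terms_cpp(coords, rep(1, max(1L, nrow(coords) - 1L)), params$k_s,
                   params$k_theta, params$epsilon, params$delta)$exclude
}

#' Analytic gradient of the conformational energy
#'
#' Partial derivatives of [total_energy()] with respect to every end-point
#' coordinate. Agrees with central finite differences away from degenerate
#' geometry (zero-length bonds, coincident excluded-volume pairs), where
#' an error is raised instead.
#'
#' @inheritParams total_energy
#' @return Numeric `(n + 1) x 3` gradient matrix, in `kBT` per reduced
#'   length unit.
#' @export
energy_gradient <- function(coords, model, params = energy_params()) {
  coords <- as_conformation(coords, model)
  energy_gradient_cpp(coords, model$rest_lengths, params$k_s,
                      params$k_theta, params$epsilon, params$delta)
}
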