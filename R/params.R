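#' Conformational-energy parameters
#'
#' Parameters of the bead-spring polymer energy in reduced units: the
#' excluded-volume size \eqn{\delta} is the unit of length (1 reduced unit
#' corresponds to 30 nm of chromatin fiber) and the thermal energy
#' \eqn{k_B T} is the unit of energy.
#'
#' @param kBT thermal energy (reduced; default 1).
#' @param delta excluded-volume (Lennard-Jones) size parameter in reduced
#'   length units (default 1, i.e. 30 nm).
#' @param epsilon excluded-volume energy parameter in units of `kBT`
#'   (default 1).
#' @param k_s bond spring constant in units of `kBT / delta^2`
#'   (default 500).
#' @param k_theta bending constant in units of `kBT / rad^2` (default 4).
#' @param packing_density chromatin-fiber packing density in bp per nm
#'   (default 130).
#' @param length_scale_nm physical length of one reduced unit in nm
#'   (default 30).
#'
#' @return An object of class `energy_params`.
#' @examples
#' p <- energy_params()
#' p$k_s
#' @export
energy_params <- function(kBT = 1, delta = 1, epsilon = 1, k_s = 500,
                          k_theta = 4, packing_density = 130,
                          length_scale_nm = 30) {
  p <- list(kBT = kBT, delta = delta, epsilon = epsilon, k_s = k_s,
            k_theta = k_theta, packing_density = packing_density,
            length_scale_nm = length_scale_nm)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("energy_params: '", nm, "' must be a single positive number")
  }
  structure(p, class = "energy_params")
}

#' @export
print.energy_params <- function(x, ...) {
  cat("Conformational energy parameters (reduced units):\n")
  cat(sprintf("  kBT = %g, delta = %g (%g nm), epsilon = %g kBT\n",
              x$kBT, x$delta, x$delta * x$length_scale_nm, x$epsilon))
  cat(sprintf("  k_s = %g kBT/delta^2, k_theta = %g kBT/rad^2\n",
              x$k_s, x$k_theta))
  cat(sprintf("  packing density = %g bp/nm\n", x$packing_density))
  invisible(x)
}

#' SI values of the energy parameters
#'
#' Converts the reduced-unit energy parameters to SI units at a given
#' absolute temperature, using \eqn{k_B = 1.380649 \times 10^{-23}} J/K.
#'
#' @param params an [energy_params()] object.
#' @param temperature absolute temperature in kelvin (default 300).
#' @return Named list with `kBT_joule`, `delta_nm`, `epsilon_joule`,
#'   `k_s_joule_per_m2` and `k_theta_joule_per_rad2`.
#' @examples
#' si_parameters(energy_params())$kBT_joule  # ~4.1e-21 J at 300 K
#' @export
si_parameters <- function(params = energy_params(), temperature = 300) {
  kB <- 1.380649e-23
  kbt <- kB * temperature * params$kBT
  delta_m <- params$delta * params$length_scale_nm * 1e-9
  list(kBT_joule = kbt,
       delta_nm = params$delta * params$length_scale_nm,
       epsilon_joule = params$epsilon * kbt,
       k_s_joule_per_m2 = params$k_s * kbt / delta_m^2,
       k_theta_joule_per_rad2 = params$k_theta * kbt)
}
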