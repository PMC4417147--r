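#' Ensemble of weighted conformations
#'
#' A chromosome is represented not by one consensus structure but by an
#' ensemble \eqn{\{(S_i, w_i)\}_{i=1..k}} of conformations with
#' normalized weights, reflecting both cell-to-cell heterogeneity in the
#' population-averaged 3C signal and uncertainty in the data.
#'
#' @param conformations list of `k` conformation matrices.
#' @param weights numeric vector of `k` weights in `[0, 1]` summing to 1
#'   within 1e-9.
#' @param log_likelihoods numeric vector of `k` per-structure
#'   log-posterior values.
#' @return An object of class `ensemble_state`.
#' @export
ensemble_state <- function(conformations, weights = NULL,
                           log_likelihoods = NULL) {
  stopifnot(is.list(conformations), length(conformations) >= 1L)
  k <- length(conformations)
  conformations <- lapply(conformations, as_conformation)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (is.null(log_likelihoods)) log_likelihoods <- rep(NA_real_, k)
  if (length(weights) != k || length(log_likelihoods) != k)
    stop("weights and log_likelihoods must have one entry per conformation")
  if (any(weights < -1e-12) || any(weights > 1 + 1e-12))
    stop("weights must lie in [0, 1]")
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", sum(weights), ")")
  structure(list(conformations = conformations,
                 weights = as.numeric(weights),
                 log_likelihoods = as.numeric(log_likelihoods)),
            class = "ensemble_state")
}

#' @export
print.ensemble_state <- function(x, ...) {
  cat(sprintf("Structure ensemble: k = %d members, %d end points each\n",
              length(x$conformations), nrow(x$conformations[[1L]])))
  cat(sprintf("  max weight %.3g (member %d)\n", max(x$weights),
              which.max(x$weights)))
  invisible(x)
}

#' Nuisance parameters of the Bayesian model
#'
#' @param alpha frequency-to-distance conversion exponent, > 0.
#' @param sigma standard deviation of the Gaussian restraint noise in
#'   reduced length units, > 0.
#' @return An object of class `nuisance_params`.
#' @export
nuisance_params <- function(alpha, sigma) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop("alpha must be a single positive number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number")
  structure(list(alpha = alpha, sigma = sigma), class = "nuisance_params")
}

#' Back-compute restraint distances from a conformation
#'
#' For each restraint record `(i, j)` returns the Euclidean distance
#' between the midpoints of fragments `i` and `j`, the points where a 3C
#' ligation event is localized.
#'
#' @param coords conformation matrix.
#' @param model a [segment_model()].
#' @param restraints a `restraint_set` (see [convert_frequencies()]).
#' @return Numeric vector of `m` back-computed distances (reduced units).
#' @export
back_compute_distances <- function(coords, model, restraints) {
  coords <- as_conformation(coords, model)
  if (any(restraints$i < 1L) || any(restraints$j > model$n))
    stop("restraint indices out of range for the model")
  backcompute_cpp(coords, as.integer(restraints$i) - 1L,
                  as.integer(restraints$j) - 1L)
}

#' Log-posterior of a single conformation
#'
#' The per-structure objective combines a Boltzmann prior on the
#' conformational energy, a Gaussian restraint likelihood and Jeffreys
#' priors on the nuisance parameters:
#' \deqn{L(S \mid D, \sigma, \alpha) = -\log\sigma - \log\alpha
#'   - E_S / k_B T
#'   - \frac{1}{2\sigma^2}\sum_{i=1}^m (D_i^S - D_i)^2 - m \log\sigma,}
#' where \eqn{D_i = \beta F_i^{-\alpha}} are the targets re-converted at
#' the current \eqn{\alpha} and \eqn{D_i^S} the back-computed distances.
#'
#' @param coords conformation matrix.
#' @param model a [segment_model()].
#' @param restraints a `restraint_set`.
#' @param eparams an [energy_params()] object.
#' @param nuisance a [nuisance_params()] object.
#' @return Scalar log-posterior (up to a constant).
#' @export
log_posterior <- function(coords, model, restraints, eparams = energy_params(),
                          nuisance) {
  stopifnot(inherits(nuisance, "nuisance_params"))
  if (!nrow(restraints)) stop("restraint set is empty")
  restraints <- restraint_targets(restraints, nuisance$alpha)
  ds <- back_compute_distances(coords, model, restraints)
  es <- total_energy(coords, model, eparams)
  m <- nrow(restraints)
  -log(nuisance$sigma) - log(nuisance$alpha) - es / eparams$kBT -
    sum((ds - restraints$D)^2) / (2 * nuisance$sigma^2) -
    m * log(nuisance$sigma)
}

#' Gradient of the log-posterior with respect to the coordinates
#'
#' \eqn{-\nabla E_S / k_B T - (1/\sigma^2) \sum_i (D_i^S - D_i)
#' \nabla D_i^S}; the terms in the nuisance parameters do not depend on
#' the coordinates.
#'
#' @inheritParams log_posterior
#' @return Numeric `(n + 1) x 3` gradient matrix.
#' @export
posterior_gradient <- function(coords, model, restraints,
                               eparams = energy_params(), nuisance) {
  stopifnot(inherits(nuisance, "nuisance_params"))
  coords <- as_conformation(coords, model)
  restraints <- restraint_targets(restraints, nuisance$alpha)
  g <- -energy_gradient(coords, model, eparams) / eparams$kBT
  if (nrow(restraints)) {
    g <- g + data_gradient_cpp(coords, as.integer(restraints$i) - 1L,
                               as.integer(restraints$j) - 1L,
                               restraints$D, nuisance$sigma)
  }
  g
}

#' Normalized ensemble weights from log-likelihoods
#'
#' Softmax in log space: \eqn{w_i = \exp(L_i - \mathrm{logsumexp}(L))}.
#' Invariant to adding a constant to all `L_i`, and numerically safe for
#' the large-magnitude log-posteriors that arise at chromosome scale.
#'
#' @param log_likelihoods numeric vector of finite per-structure
#'   log-likelihood values.
#' @return Weight vector summing to 1.
#' @examples
#' compute_weights(c(0, log(3)))  # 0.25, 0.75
#' @export
compute_weights <- function(log_likelihoods) {
  if (!length(log_likelihoods)) stop("need at least one log-likelihood")
  if (any(!is.finite(log_likelihoods)))
    stop("log-likelihoods must all be finite")
  z <- log_likelihoods - max(log_likelihoods)
  w <- exp(z)
  w / sum(w)
}

#' Ensemble likelihood
#'
#' The weighted mean per-structure log-likelihood,
#' \eqn{L = \sum_i L_i w_i}. This is the objective maximized by the
#' M step and monitored for EM convergence.
#'
#' @param log_likelihoods numeric vector of `k` values.
#' @param weights normalized weight vector of the same length.
#' @return Scalar ensemble likelihood.
#' @export
ensemble_likelihood <- function(log_likelihoods, weights) {
  if (length(log_likelihoods) != length(weights))
    stop("log_likelihoods and weights must have equal length")
  sum(log_likelihoods * weights)
}
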