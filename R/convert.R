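#' Frequency-to-distance conversion parameters
#'
#' The spatial distance between two loci is taken to be inversely related
#' to their interaction frequency through the power law
#' \eqn{D = \beta F^{-\alpha}}: `alpha` is the (dimensionless) exponent,
#' estimated by the EM algorithm, and `beta` is a scale in reduced length
#' units, calibrated once from sequence-adjacent fragment pairs (see
#' [calibrate_beta()]).
#'
#' @param alpha power-law exponent, > 0.
#' @param beta scale factor in reduced length units, > 0.
#' @param min_freq pairs with frequency at or below this value yield no
#'   restraint (default 0: only strictly positive frequencies are used).
#' @return An object of class `conversion_params`.
#' @export
conversion_params <- function(alpha, beta, min_freq = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("alpha must be a single non-negative number")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a single positive number")
  if (!is.numeric(min_freq) || length(min_freq) != 1L || min_freq < 0)
    stop("min_freq must be a single non-negative number")
  structure(list(alpha = alpha, beta = beta, min_freq = min_freq),
            class = "conversion_params")
}

#' Convert interaction frequencies to distance restraints
#'
#' Builds one distance restraint per fragment pair `(i, j)`, `i < j`, with
#' frequency above `min_freq`: the target distance is
#' \eqn{D = \beta F^{-\alpha}}. Pairs at or below `min_freq` are omitted
#' entirely -- an unobserved contact is censored data, not evidence of a
#' large distance.
#'
#' @param fm a [frequency_matrix()].
#' @param cp a [conversion_params()] object.
#' @return An object of class `restraint_set`: a data frame with columns
#'   `i`, `j` (1-based fragment indices), `F` (frequency) and `D` (target
#'   distance, reduced units), carrying `alpha` and `beta` as attributes.
#' @examples
#' fm <- frequency_matrix(rbind(c(0, 4, 1), c(4, 0, 2), c(1, 2, 0)))
#' convert_frequencies(fm, conversion_params(alpha = 0.5, beta = 1))
#' @export
convert_frequencies <- function(fm, cp) {
  stopifnot(inherits(fm, "frequency_matrix"), inherits(cp, "conversion_params"))
  idx <- which(upper.tri(fm$values), arr.ind = TRUE)
  f <- fm$values[idx]
  keep <- f > cp$min_freq
  if (!any(keep))
    stop("no fragment pair has frequency above min_freq = ", cp$min_freq)
  rec <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L], F = f[keep])
  rec <- rec[order(rec$i, rec$j), , drop = FALSE]
  rownames(rec) <- NULL
  rec$D <- cp$beta * rec$F^(-cp$alpha)
  structure(rec, class = c("restraint_set", "data.frame"),
            alpha = cp$alpha, beta = cp$beta)
}

#' Re-evaluate restraint targets at a new exponent
#'
#' Recomputes the `D` column of a restraint set as
#' \eqn{\beta F^{-\alpha}} for a new `alpha`, keeping the calibrated
#' `beta` fixed.
#'
#' @param restraints a `restraint_set`.
#' @param alpha new exponent.
#' @return The updated restraint set.
#' @export
restraint_targets <- function(restraints, alpha) {
  beta <- attr(restraints, "beta")
  restraints$D <- beta * restraints$F^(-alpha)
  attr(restraints, "alpha") <- alpha
  restraints
}

#' Calibrate the conversion scale from adjacent fragment pairs
#'
#' Sequence-adjacent fragments are physically connected, so their spatial
#' distance is commensurate with the segment rest lengths. `beta` is
#' chosen so that the mean converted distance
#' \eqn{\beta F_{i,i+1}^{-\alpha}} over observed adjacent pairs equals a
#' reference adjacent-pair distance:
#' \eqn{\beta = \bar{l}_{ref} / \mathrm{mean}(F_{adj}^{-\alpha})}.
#' By default the reference is the mean segment rest length. [run_em()]
#' instead passes the mean adjacent midpoint distance of its Brownian
#' starting pool, which accounts for the systematic shortening of
#' midpoint separations by thermal bending fluctuations.
#'
#' @param fm a [frequency_matrix()].
#' @param model a [segment_model()] with `fm$n` segments.
#' @param alpha conversion exponent at which to calibrate.
#' @param reference_length reference mean adjacent-pair distance in
#'   reduced units (default: mean rest length of the model).
#' @return The calibrated `beta` (reduced length units).
#' @export
calibrate_beta <- function(fm, model, alpha,
                           reference_length = mean(model$rest_lengths)) {
  stopifnot(inherits(fm, "frequency_matrix"))
  if (fm$n != model$n)
    stop("frequency matrix has ", fm$n, " fragments but the model has ",
         model$n)
  i <- seq_len(fm$n - 1L)
  fadj <- fm$values[cbind(i, i + 1L)]
  fadj <- fadj[fadj > 0]
  if (!length(fadj))
    stop("no sequence-adjacent pair with positive frequency; cannot calibrate")
  if (!is.numeric(reference_length) || reference_length <= 0)
    stop("reference_length must be positive")
  reference_length / mean(fadj^(-alpha))
}
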