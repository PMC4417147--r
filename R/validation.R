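#' Pearson product-moment correlation
#'
#' @param x,y numeric vectors of equal length (at least 2) with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  cor(x, y)
}

#' Seeded k-fold partition of restraint records
#'
#' @param m number of restraint records, or a `restraint_set`.
#' @param folds number of folds (>= 2).
#' @param seed RNG seed.
#' @return Integer vector of fold labels (1..folds), fold sizes differing
#'   by at most one.
#' @export
kfold_split <- function(m, folds, seed = 1L) {
  if (inherits(m, "restraint_set") || is.data.frame(m)) m <- nrow(m)
  m <- as.integer(m)
  folds <- as.integer(folds)
  if (folds < 2L) stop("folds must be at least 2")
  if (folds > m) stop("more folds (", folds, ") than records (", m, ")")
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = m))
}

#' Cross-validate the ensemble inference
#'
#' Partitions the restraint records into `folds` subsets; for each fold,
#' the EM inference runs on the remaining records only, and the held-out
#' records are scored by comparing the ensemble-weighted mean
#' back-computed distance against the expected distance
#' \eqn{\beta F^{-\hat\alpha}} at the exponent fitted on the training
#' folds. Per-fold and pooled Pearson correlations are reported.
#'
#' @param fm a [frequency_matrix()].
#' @param fragment_table fragment-table path, data frame or
#'   [segment_model()].
#' @param config an [inference_config()]; fold `f` runs with seed
#'   `config$seed + f`.
#' @param folds number of folds (default 10).
#' @param eparams an [energy_params()] object.
#' @param min_freq restraint frequency threshold (default 0).
#' @return An object of class `cv_report`: list with `assignments`,
#'   `per_fold` (data frame: fold, n_test, correlation, alpha, sigma),
#'   `pooled` (data frame of predicted/expected pairs) and
#'   `pooled_correlation`.
#' @export
cross_validate <- function(fm, fragment_table, config = inference_config(),
                           folds = 10, eparams = energy_params(),
                           min_freq = 0) {
  model <- if (inherits(fragment_table, "segment_model")) fragment_table
           else build_segment_model(fragment_table, eparams)
  # enumerate restraint records exactly as convert_frequencies does
  full <- convert_frequencies(fm, conversion_params(1, 1, min_freq))
  m <- nrow(full)
  assign <- kfold_split(m, folds, seed = config$seed)
  per_fold <- NULL
  pooled <- NULL
  for (f in seq_len(folds)) {
    train <- which(assign != f)
    test <- which(assign == f)
    cfg_f <- config
    cfg_f$seed <- (config$seed + f) %% .Machine$integer.max
    fit <- run_em(fm, model, cfg_f, eparams, min_freq,
                  restraint_subset = train)
    test_rec <- full[test, , drop = FALSE]
    Ds <- vapply(fit$ensemble$conformations, function(x)
      backcompute_cpp(as_conformation(x, model),
                      as.integer(test_rec$i) - 1L,
                      as.integer(test_rec$j) - 1L),
      numeric(length(test)))
    pred <- as.numeric(matrix(Ds, nrow = length(test)) %*%
                         fit$ensemble$weights)
    expected <- fit$beta * test_rec$F^(-fit$nuisance$alpha)
    rho <- if (length(test) >= 2L && stats::sd(pred) > 0 &&
               stats::sd(expected) > 0) cor(pred, expected) else NA_real_
    per_fold <- rbind(per_fold, data.frame(
      fold = f, n_test = length(test), correlation = rho,
      alpha = fit$nuisance$alpha, sigma = fit$nuisance$sigma))
    pooled <- rbind(pooled, data.frame(fold = f, i = test_rec$i,
                                       j = test_rec$j, predicted = pred,
                                       expected = expected))
  }
  structure(list(assignments = assign, per_fold = per_fold, pooled = pooled,
                 pooled_correlation = pearson_correlation(pooled$predicted,
                                                          pooled$expected)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d restraints\n",
              nrow(x$per_fold), length(x$assignments)))
  cat(sprintf("  pooled predicted-vs-expected correlation: %.3f\n",
              x$pooled_correlation))
  cat(sprintf("  per-fold correlations: %s\n",
              paste(sprintf("%.3f", x$per_fold$correlation), collapse = " ")))
  invisible(x)
}

#' Optimal rigid-body superposition (Kabsch/SVD)
#'
#' Finds the proper rotation and translation of `mobile` minimizing the
#' coordinate RMSD to `ref`, using the SVD of the cross-covariance matrix
#' with the usual determinant sign correction so that reflections are
#' never applied.
#'
#' @param ref,mobile conformation matrices with equal point counts.
#' @return List with `aligned` (the transformed mobile coordinates) and
#'   `rmsd`.
#' @export
kabsch_align <- function(ref, mobile) {
  ref <- as_conformation(ref)
  mobile <- as_conformation(mobile)
  if (nrow(ref) != nrow(mobile))
    stop("point counts differ: ", nrow(ref), " vs ", nrow(mobile))
  cr <- colMeans(ref)
  cm <- colMeans(mobile)
  Y <- sweep(ref, 2, cr)
  X <- sweep(mobile, 2, cm)
  H <- crossprod(X, Y)                      # sum_i x_i y_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((aligned - Y)^2)))
  aligned <- sweep(aligned, 2, cr, "+")
  list(aligned = aligned, rmsd = rmsd)
}

#' Superpose all ensemble members onto the highest-weight member
#'
#' @param ensemble an [ensemble_state()].
#' @return The ensemble with every member rigidly superposed onto the
#'   member of largest weight (ties broken by member index); the reference
#'   member itself is unchanged. Weights and log-likelihoods are
#'   preserved.
#' @export
align_ensemble <- function(ensemble) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  ref_idx <- which.max(ensemble$weights)   # first maximum: lowest index
  ref <- ensemble$conformations[[ref_idx]]
  confs <- lapply(seq_along(ensemble$conformations), function(i) {
    if (i == ref_idx) return(ensemble$conformations[[i]])
    kabsch_align(ref, ensemble$conformations[[i]])$aligned
  })
  ensemble_state(confs, ensemble$weights, ensemble$log_likelihoods)
}

# Map a genomic bp position to a 3D point by linear interpolation within
# its containing fragment; cut sites map exactly to chain end points.
bp_to_point <- function(coords, model, bp) {
  lo <- model$spans[1L, 1L]
  hi <- model$spans[model$n, 2L]
  if (bp < lo || bp > hi)
    stop("position ", bp, " outside the modeled span [", lo, ", ", hi, "]")
  if (bp == hi) return(coords[model$n + 1L, ])
  i <- findInterval(bp, model$spans[, 1L])
  frac <- (bp - model$spans[i, 1L]) / model$bp_lengths[i]
  coords[i, ] + frac * (coords[i + 1L, ] - coords[i, ])
}

#' Ensemble-expected distance between two genomic positions
#'
#' Each bp position is mapped onto the chain by linear interpolation
#' within its fragment; the reported distance is the ensemble-weighted
#' mean of the per-member Euclidean distances, converted to nm.
#'
#' @param ensemble an [ensemble_state()].
#' @param model a [segment_model()].
#' @param eparams an [energy_params()] object.
#' @param bp_a,bp_b genomic positions in bp within the modeled span.
#' @return Expected spatial distance in nm.
#' @export
expected_distance <- function(ensemble, model, eparams = energy_params(),
                              bp_a, bp_b) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  d <- vapply(ensemble$conformations, function(x) {
    x <- as_conformation(x, model)
    pa <- bp_to_point(x, model, bp_a)
    pb <- bp_to_point(x, model, bp_b)
    sqrt(sum((pa - pb)^2))
  }, numeric(1))
  sum(ensemble$weights * d) * eparams$length_scale_nm
}

#' Count close long-range fragment pairs
#'
#' Lists all fragment midpoint pairs at least `min_sep_segments` apart
#' along the sequence whose ensemble-expected spatial distance falls in
#' `[dmin_nm, dmax_nm]` -- the operational definition of a long-range
#' spatial contact.
#'
#' @inheritParams expected_distance
#' @param min_sep_segments minimum sequence separation in segments
#'   (default 5).
#' @param dmin_nm,dmax_nm distance window in nm (defaults 45 and 100).
#' @return List with `pairs` (data frame: i, j, distance_nm) and `count`.
#' @export
contact_pairs <- function(ensemble, model, eparams = energy_params(),
                          min_sep_segments = 5, dmin_nm = 45,
                          dmax_nm = 100) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  n <- model$n
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[idx[, 2L] - idx[, 1L] >= min_sep_segments, , drop = FALSE]
  if (!nrow(idx))
    return(list(pairs = data.frame(i = integer(), j = integer(),
                                   distance_nm = numeric()), count = 0L))
  Ds <- vapply(ensemble$conformations, function(x)
    backcompute_cpp(as_conformation(x, model), idx[, 1L] - 1L,
                    idx[, 2L] - 1L), numeric(nrow(idx)))
  dnm <- as.numeric(matrix(Ds, nrow = nrow(idx)) %*% ensemble$weights) *
    eparams$length_scale_nm
  keep <- dnm >= dmin_nm & dnm <= dmax_nm
  pairs <- data.frame(i = idx[keep, 1L], j = idx[keep, 2L],
                      distance_nm = dnm[keep])
  rownames(pairs) <- NULL
  list(pairs = pairs, count = nrow(pairs))
}

#' Fit a saturating distance-vs-separation curve
#'
#' Least-squares fit of \eqn{d(s) = d_{max}(1 - e^{-s/s_0})} to
#' spatial-distance versus sequence-separation pairs. The saturating form
#' captures the leveling-off of spatial distance at large genomic
#' separation imposed by the confinement of the chromosome territory.
#'
#' @param s sequence separations (bp).
#' @param d spatial distances (nm).
#' @return List with `d_max` (nm), `s0` (bp) and `residual` (sum of
#'   squared residuals).
#' @export
fit_saturating_curve <- function(s, d) {
  if (length(s) != length(d)) stop("s and d must have equal length")
  if (length(unique(s)) < 3L)
    stop("need at least 3 distinct sequence separations")
  df <- data.frame(s = as.numeric(s), d = as.numeric(d))
  fit <- tryCatch(
    minpack.lm::nlsLM(d ~ dmax * (1 - exp(-s / s0)), data = df,
                      start = list(dmax = max(df$d), s0 = median(df$s) / 2),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("distance-curve fit failed: ",
                             conditionMessage(e)))
  co <- coef(fit)
  list(d_max = unname(co["dmax"]), s0 = unname(co["s0"]),
       residual = sum(stats::residuals(fit)^2))
}

#' @describeIn fit_saturating_curve Fit the curve to all fragment-midpoint
#'   pairs of an ensemble: separation is the bp distance between fragment
#'   midpoints, distance the ensemble-expected spatial distance in nm.
#' @inheritParams expected_distance
#' @export
fit_distance_curve <- function(ensemble, model, eparams = energy_params()) {
  n <- model$n
  mid_bp <- rowMeans(model$spans)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Ds <- vapply(ensemble$conformations, function(x)
    backcompute_cpp(as_conformation(x, model), idx[, 1L] - 1L,
                    idx[, 2L] - 1L), numeric(nrow(idx)))
  dnm <- as.numeric(matrix(Ds, nrow = nrow(idx)) %*% ensemble$weights) *
    eparams$length_scale_nm
  s <- abs(mid_bp[idx[, 2L]] - mid_bp[idx[, 1L]])
  fit_saturating_curve(s, dnm)
}
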