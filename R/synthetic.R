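#' Specification of a synthetic test instance
#'
#' Describes a self-contained synthetic data set with the statistical
#' structure the inference assumes: a chain of restriction fragments, a
#' small ground-truth ensemble of conformations drawn from the
#' conformational-energy distribution, and an interaction-frequency
#' matrix obtained by inverting the power-law conversion on noisy
#' ensemble-averaged distances. Defaults emulate a yeast-chromosome-scale
#' instance: 20 fragments of 1-40 kb, \eqn{\alpha^* = 0.5},
#' \eqn{\sigma^* = 0.1} reduced units, 5 ground-truth conformations.
#'
#' @param n_segments number of fragments (default 20).
#' @param bp_lengths optional fixed fragment lengths in bp; by default
#'   drawn log-uniformly from 1-40 kb under `seed`.
#' @param alpha true conversion exponent (default 0.5).
#' @param beta true conversion scale in reduced units, or `"calibrated"`
#'   (default) for the mean segment rest length, which keeps adjacent-pair
#'   frequencies near 1 and makes the pre-EM scale calibration consistent
#'   with the generator.
#' @param noise_sigma distance-space noise standard deviation in reduced
#'   units (default 0.1).
#' @param k_truth number of ground-truth conformations averaged
#'   (default 5), mimicking the population averaging of 3C measurements.
#' @param seed RNG seed (required; the instance is a pure function of the
#'   spec).
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_segments = 20, bp_lengths = NULL, alpha = 0.5,
                           beta = "calibrated", noise_sigma = 0.1,
                           k_truth = 5, seed = 1L) {
  stopifnot(n_segments >= 2, alpha > 0, noise_sigma >= 0, k_truth >= 1)
  if (!identical(beta, "calibrated") && (!is.numeric(beta) || beta <= 0))
    stop("beta must be a positive number or \"calibrated\"")
  structure(list(n_segments = as.integer(n_segments),
                 bp_lengths = bp_lengths, alpha = alpha, beta = beta,
                 noise_sigma = noise_sigma, k_truth = as.integer(k_truth),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a ground-truth chain and conformations
#'
#' Draws the fragment lengths (if not fixed in the spec), builds the
#' segment model and samples `k_truth` conformations from the
#' conformational-energy distribution by Brownian simulation with the
#' default confinement. Deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @param eparams an [energy_params()] object.
#' @param brownian_steps Langevin steps per ground-truth conformation
#'   (default 50000).
#' @return List with `model` (a [segment_model()]), `truths` (list of
#'   conformations) and `beta` (the resolved numeric true scale).
#' @export
generate_truth <- function(spec, eparams = energy_params(),
                           brownian_steps = 50000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  bp <- spec$bp_lengths
  if (is.null(bp))
    bp <- round(exp(runif(spec$n_segments, log(1000), log(40000))))
  if (length(bp) != spec$n_segments)
    stop("bp_lengths must have n_segments entries")
  ends <- cumsum(bp)
  model <- segment_model(cbind(c(0, ends[-length(ends)]), ends),
                         chrom = "chrS", params = eparams)
  cfg <- inference_config(k = spec$k_truth, seed = spec$seed,
                          brownian_steps = brownian_steps)
  truths <- brownian_initialize(model, eparams, cfg, seed = NULL)
  beta <- if (identical(spec$beta, "calibrated"))
    mean(model$rest_lengths) else spec$beta
  list(model = model, truths = truths, beta = beta)
}

#' Simulate an interaction-frequency matrix from ground-truth structures
#'
#' For every fragment pair, the ensemble-mean midpoint distance
#' \eqn{\bar D} receives additive Gaussian noise (truncated below at
#' \eqn{0.05 \bar D} so distances stay positive) and is inverted through
#' the conversion law: \eqn{F = (D' / \beta)^{-1/\alpha}}. With
#' `noise_sigma = 0` the construction is exactly inverted by
#' [convert_frequencies()] at the true parameters.
#'
#' @param model a [segment_model()].
#' @param truths list of ground-truth conformations.
#' @param spec a [synthetic_spec()]; the noise draw is seeded with
#'   `spec$seed + 1`.
#' @param beta numeric true scale (as resolved by [generate_truth()]).
#' @return A [frequency_matrix()].
#' @export
simulate_frequencies <- function(model, truths, spec,
                                 beta = mean(model$rest_lengths)) {
  stopifnot(inherits(spec, "synthetic_spec"), length(truths) >= 1L)
  set.seed(spec$seed + 1L)
  n <- model$n
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  Ds <- vapply(truths, function(x)
    backcompute_cpp(as_conformation(x, model), idx[, 1L] - 1L,
                    idx[, 2L] - 1L), numeric(nrow(idx)))
  dbar <- rowMeans(matrix(Ds, nrow = nrow(idx)))
  dnoisy <- dbar + rnorm(length(dbar), sd = spec$noise_sigma)
  dnoisy <- pmax(dnoisy, 0.05 * dbar)
  f <- (dnoisy / beta)^(-1 / spec$alpha)
  vals <- matrix(0, n, n)
  vals[idx] <- f
  vals[idx[, c(2L, 1L), drop = FALSE]] <- f
  frequency_matrix(vals)
}

#' Write a complete synthetic fixture to disk
#'
#' Generates the ground truth and frequencies and writes a fragment table
#' (`fragments.tsv`), a square-dialect frequency matrix (`matrix.tsv`),
#' the ground-truth structures (`truth_###.xyz`) and a `manifest.json`
#' recording the true \eqn{\alpha, \beta, \sigma} and seed, so that tests
#' can score parameter recovery.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory (created if missing).
#' @param eparams an [energy_params()] object.
#' @return Invisibly, a list of the written paths plus the generated
#'   `model`, `truths` and `fm`.
#' @export
make_fixture <- function(spec, out_dir, eparams = energy_params()) {
  truth <- generate_truth(spec, eparams)
  fm <- simulate_frequencies(truth$model, truth$truths, spec,
                             beta = truth$beta)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  frag_path <- file.path(out_dir, "fragments.tsv")
  write.table(data.frame(chrom = truth$model$chrom,
                         start = truth$model$spans[, 1L],
                         end = truth$model$spans[, 2L]),
              frag_path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  mat_path <- file.path(out_dir, "matrix.tsv")
  write_frequency_matrix(fm, mat_path)
  truth_paths <- vapply(seq_along(truth$truths), function(i) {
    p <- file.path(out_dir, sprintf("truth_%03d.xyz", i))
    write_structure(truth$truths[[i]], eparams, p, "xyz")
    p
  }, character(1))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(
    list(n_segments = truth$model$n, alpha = spec$alpha, beta = truth$beta,
         noise_sigma = spec$noise_sigma, k_truth = spec$k_truth,
         seed = spec$seed),
    manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(fragments = frag_path, matrix = mat_path,
                 truths = truth_paths, manifest = manifest_path,
                 model = truth$model, truth_confs = truth$truths, fm = fm))
}
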