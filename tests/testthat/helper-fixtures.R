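# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests themselves write to tempdir().

# Chain of n equal fragments; bp chosen so the rest length is `rest`
# reduced units (default 2: bonded beads sit beyond the WCA cutoff, so a
# straight chain at rest is exactly zero-energy).
test_model <- function(n = 5, rest = 2, params = energy_params()) {
  bp <- rest * params$packing_density * params$length_scale_nm
  ends <- cumsum(rep(bp, n))
  segment_model(cbind(c(0, ends[-n]), ends), chrom = "chrT",
                params = params)
}

# Straight chain along x with the model's rest lengths.
straight_chain <- function(model) {
  x <- c(0, cumsum(model$rest_lengths))
  cbind(x, 0, 0)
}

# Mildly perturbed chain: never degenerate, bends and stretches a bit.
wobbly_chain <- function(model, sd = 0.15) {
  straight_chain(model) + matrix(rnorm(3 * (model$n + 1), sd = sd),
                                 ncol = 3)
}

random_rigid_motion <- function() {
  q <- matrix(rnorm(9), 3)
  R <- qr.Q(qr(q))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(coords, rm) {
  sweep(coords %*% t(rm$R), 2, rm$t, "+")
}

# Central finite differences of a scalar function of the coordinates.
fd_gradient <- function(f, coords, h = 1e-6) {
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (j in 1:3) {
      xp <- coords; xp[i, j] <- xp[i, j] + h
      xm <- coords; xm[i, j] <- xm[i, j] - h
      g[i, j] <- (f(xp) - f(xm)) / (2 * h)
    }
  }
  g
}

# A small EM-ready instance: model + frequency matrix simulated from a
# known ground truth. Kept tiny so unit tests stay fast; the acceptance
# tests use the full default spec.
small_instance <- function(seed = 5, n = 8, noise = 0, k_truth = 3) {
  spec <- synthetic_spec(n_segments = n, noise_sigma = noise,
                         k_truth = k_truth, seed = seed)
  tr <- generate_truth(spec, brownian_steps = 10000)
  fm <- simulate_frequencies(tr$model, tr$truths, spec, beta = tr$beta)
  list(spec = spec, model = tr$model, truths = tr$truths, beta = tr$beta,
       fm = fm)
}

# Small-footprint inference configuration for unit tests (NOT the study
# conditions; those live in the acceptance tests).
tiny_config <- function(seed = 1, k = 3, ...) {
  inference_config(k = k, seed = seed, brownian_steps = 4000,
                   max_em_iter = 4, ...)
}
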