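test_that("inference config validates grids and defaults", {
  cfg <- inference_config()
  expect_equal(cfg$k, 200L)
  expect_equal(cfg$max_em_iter, 20L)
  expect_equal(cfg$alpha_grid$coarse_step, (1.5 - 0.1) / 9)
  expect_equal(cfg$alpha_grid$fine_step, 2 * (1.5 - 0.1) / 9 / 9)
  expect_error(inference_config(k = 0), "at least 1")
  expect_error(inference_config(alpha_grid = list(lo = 2, hi = 1)),
               "hi > lo")
})

test_that("Brownian initialization is seeded, confined and equilibrated", {
  m <- test_model(6, rest = 1.5)
  cfg <- tiny_config(seed = 21, k = 3)
  a <- brownian_initialize(m, energy_params(), cfg)
  b <- brownian_initialize(m, energy_params(), cfg)
  expect_identical(a, b)                       # bit-identical under a seed
  radius <- sum(m$rest_lengths) / 4
  for (x in a) {
    expect_true(all(sqrt(rowSums(x^2)) <= radius + 1e-9))
    expect_true(is.finite(total_energy(x, m)))
  }
})

test_that("Brownian equilibrium reproduces the stretch-term statistics", {
  # bonds at rest length 2 (no bonded WCA conflict): thermal bond-length
  # fluctuations have sd sqrt(kBT/k_s) ~ 0.045, so the mean bond length
  # over many members must sit within 10% of the mean rest length
  m <- test_model(6, rest = 2)
  cfg <- inference_config(k = 50, seed = 22, brownian_steps = 10000)
  pool <- brownian_initialize(m, energy_params(), cfg)
  mb <- mean(vapply(pool, function(x) mean(segment_lengths(x)), numeric(1)))
  expect_lt(abs(mb - mean(m$rest_lengths)) / mean(m$rest_lengths), 0.1)
})

test_that("structure optimization never worsens and recovers noiseless targets", {
  inst <- small_instance(seed = 23, n = 10)
  m <- inst$model
  cfg <- tiny_config(seed = 23)
  # targets back-computed from a known structure, no noise
  truth <- inst$truths[[1]]
  idx <- which(upper.tri(matrix(0, m$n, m$n)), arr.ind = TRUE)
  rec <- data.frame(i = idx[, 1], j = idx[, 2], F = 1)
  rec$D <- back_compute_distances(truth, m, structure(
    rec, class = c("restraint_set", "data.frame"), beta = 1))
  rs <- structure(rec, class = c("restraint_set", "data.frame"),
                  alpha = 1, beta = 1)
  rs$F <- rs$D^(-1)                   # so re-conversion at alpha=1 is a no-op
  nu <- nuisance_params(1, 0.05)
  start <- inst$truths[[2]]
  lp0 <- log_posterior(start, m, rs, energy_params(), nu)
  out <- optimize_structure(start, m, rs, energy_params(), nu, cfg)
  lp1 <- log_posterior(out, m, rs, energy_params(), nu)
  expect_gte(lp1, lp0)
  ds <- back_compute_distances(out, m, rs)
  expect_gt(cor(ds, rs$D), 0.99)      # self-consistency recovery
  # a perfect-fit optimum is a fixed point
  again <- optimize_structure(out, m, rs, energy_params(), nu, cfg)
  expect_lt(max(abs(again - out)), 1e-4)
})

test_that("E step refines, re-weights and treats members independently", {
  inst <- small_instance(seed = 24)
  cfg <- tiny_config(seed = 24, k = 3)
  set.seed(24)
  pool <- brownian_initialize(inst$model, energy_params(), cfg, seed = NULL)
  rs <- convert_frequencies(inst$fm, conversion_params(0.5, inst$beta, 0))
  nu <- nuisance_params(0.5, 0.3)
  ens0 <- ensemble_state(pool)
  ll0 <- vapply(pool, log_posterior, numeric(1), model = inst$model,
                restraints = rs, eparams = energy_params(), nuisance = nu)
  ens1 <- e_step(ens0, inst$model, rs, energy_params(), nu, cfg)
  # no member got worse, and the ensemble likelihood did not fall
  expect_true(all(ens1$log_likelihoods >= ll0 - 1e-8))
  expect_gte(ensemble_likelihood(ens1$log_likelihoods, ens1$weights),
             ensemble_likelihood(ll0, compute_weights(ll0)))
  expect_equal(sum(ens1$weights), 1)
  # singleton ensembles carry weight exactly 1
  e1 <- e_step(ensemble_state(pool[1]), inst$model, rs, energy_params(),
               nu, cfg)
  expect_identical(e1$weights, 1)
  # permuting the input permutes the output
  ens_perm <- e_step(ensemble_state(pool[c(2, 3, 1)]), inst$model, rs,
                     energy_params(), nu, cfg)
  expect_equal(ens_perm$conformations[[3]], ens1$conformations[[1]])
  expect_equal(ens_perm$log_likelihoods[3], ens1$log_likelihoods[1])
})

test_that("M step honors the grid contract", {
  inst <- small_instance(seed = 25)
  cfg <- tiny_config(seed = 25, k = 3,
                     alpha_grid = list(lo = 0.4, hi = 0.9),
                     sigma_grid = list(lo = 0.5, hi = 8))
  set.seed(25)
  pool <- brownian_initialize(inst$model, energy_params(), cfg, seed = NULL)
  rs <- convert_frequencies(inst$fm, conversion_params(0.5, inst$beta, 0))
  nu <- nuisance_params(0.5, 0.3)
  ens <- e_step(ensemble_state(pool), inst$model, rs, energy_params(), nu,
                cfg)

  # degenerate single-point grids return that point
  cfg1 <- tiny_config(seed = 25, k = 3,
    alpha_grid = list(lo = 0.7, hi = 0.7001, coarse_step = 1,
                      fine_step = 1),
    sigma_grid = list(lo = 2, hi = 2.0001, coarse_step = 1, fine_step = 1))
  nu1 <- m_step(ens, inst$model, rs, energy_params(), cfg1, refit = FALSE)
  expect_equal(nu1$alpha, 0.7)
  expect_equal(nu1$sigma, sqrt(1 / (2 * 2)))

  # fixed-structure scan: returned objective beats every coarse grid point
  nu2 <- m_step(ens, inst$model, rs, energy_params(), cfg, refit = FALSE)
  m <- nrow(rs)
  obj_fixed <- function(alpha, wfac) {
    targ <- attr(rs, "beta") * rs$F^(-alpha)
    Ds <- vapply(ens$conformations, back_compute_distances, numeric(m),
                 model = inst$model, restraints = rs)
    ss <- colSums((matrix(Ds, nrow = m) - targ)^2)
    Es <- vapply(ens$conformations, total_energy, numeric(1),
                 model = inst$model, params = energy_params())
    sum(ens$weights * ((m + 1) / 2 * log(2 * wfac) - log(alpha) - Es -
                         wfac * ss))
  }
  best <- attr(nu2, "objective")
  for (a in seq(0.4, 0.9, by = cfg$alpha_grid$coarse_step))
    for (w in seq(0.5, 8, by = cfg$sigma_grid$coarse_step))
      expect_gte(best + 1e-9, obj_fixed(a, w))

  # monotone relative to an incumbent lying on the grid
  inc <- nuisance_params(0.4 + cfg$alpha_grid$coarse_step,
                         sqrt(1 / (2 * 0.5)))
  nu3 <- m_step(ens, inst$model, rs, energy_params(), cfg,
                incumbent = inc, refit = FALSE)
  expect_gte(attr(nu3, "objective"),
             obj_fixed(inc$alpha, 1 / (2 * inc$sigma^2)) - 1e-9)
})

test_that("refitting M step finds the exponent a brute-force profile finds", {
  inst <- small_instance(seed = 26, n = 8, noise = 0)
  cfg <- tiny_config(seed = 26, k = 4)
  set.seed(26)
  pool <- brownian_initialize(inst$model, energy_params(), cfg, seed = NULL)
  rs <- convert_frequencies(inst$fm, conversion_params(0.5, inst$beta, 0))
  nu0 <- nuisance_params(0.5, 0.3)
  ens <- e_step(ensemble_state(pool), inst$model, rs, energy_params(), nu0,
                cfg)
  got <- m_step(ens, inst$model, rs, energy_params(), cfg, incumbent = nu0)

  # independent 1-D profile: dense alpha scan, full refit per point,
  # noise weight optimized analytically on a dense grid
  m <- nrow(rs)
  profile <- function(alpha) {
    rs_a <- rs
    rs_a$D <- attr(rs, "beta") * rs$F^(-alpha)
    confs <- lapply(ens$conformations, function(x)
      optimize_structure(x, inst$model, rs_a, energy_params(),
                         nuisance_params(alpha, nu0$sigma), cfg))
    ss <- vapply(confs, function(x)
      sum((back_compute_distances(x, inst$model, rs_a) - rs_a$D)^2),
      numeric(1))
    Es <- vapply(confs, total_energy, numeric(1), model = inst$model,
                 params = energy_params())
    ws <- seq(0.1, 10, length.out = 400)
    max(vapply(ws, function(w)
      sum(ens$weights * ((m + 1) / 2 * log(2 * w) - log(alpha) - Es -
                           w * ss)), numeric(1)))
  }
  alphas <- seq(0.1, 1.5, length.out = 29)
  prof <- vapply(alphas, profile, numeric(1))
  astar <- alphas[which.max(prof)]
  expect_lt(abs(got$alpha - astar),
            cfg$alpha_grid$fine_step + diff(alphas)[1])
})

test_that("run_em is deterministic and reduces energy without restraints", {
  inst <- small_instance(seed = 27)
  cfg <- tiny_config(seed = 27, k = 3)
  f1 <- suppressWarnings(run_em(inst$fm, inst$model, cfg))
  f2 <- suppressWarnings(run_em(inst$fm, inst$model, cfg))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$nuisance, f2$nuisance)
  expect_equal(f1$ensemble$conformations, f2$ensemble$conformations)
  expect_equal(nrow(f1$trace), f1$iterations)
  expect_true(all(c("ensemble_likelihood", "alpha", "sigma",
                    "restraint_correlation") %in% names(f1$trace)))
})

test_that("optimization without data reduces the conformational energy", {
  inst <- small_instance(seed = 28)
  m <- inst$model
  cfg <- tiny_config(seed = 28, k = 3)
  set.seed(28)
  pool <- brownian_initialize(m, energy_params(), cfg, seed = NULL)
  # a restraint whose weight is negligible: data term ~ 0, prior drives
  rs <- convert_frequencies(inst$fm, conversion_params(0.5, inst$beta, 0))
  nu <- nuisance_params(0.5, 1e6)
  for (x in pool) {
    y <- optimize_structure(x, m, rs, energy_params(), nu, cfg)
    expect_lt(total_energy(y, m), total_energy(x, m))
  }
})

test_that("exponent recovery is unbiased without population averaging", {
  # a single ground-truth conformation makes the averaged targets exactly
  # realizable (up to noise), so the profile likelihood peaks at the true
  # exponent; recovery should land within one fine-grid step
  spec <- synthetic_spec(k_truth = 1, seed = 11)
  tr <- generate_truth(spec)
  fm <- simulate_frequencies(tr$model, tr$truths, spec, beta = tr$beta)
  fit <- suppressWarnings(
    run_em(fm, tr$model, inference_config(k = 20, seed = 2001)))
  expect_lt(abs(fit$nuisance$alpha - 0.5),
            inference_config()$alpha_grid$fine_step + 1e-9)
})
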