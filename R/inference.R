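#' EM inference configuration
#'
#' Settings of the ensemble-inference algorithm: the ensemble size, the
#' Brownian-dynamics initialization, the per-structure gradient ascent and
#' the \eqn{(\alpha, 1/(2\sigma^2))} grid search of the M step.
#'
#' The noise axis of the grid is parameterized as \eqn{1/(2\sigma^2)},
#' the weighting factor between the data term and the conformational
#' energy. Coarse grids span `lo`..`hi` in steps of `coarse_step`; the
#' fine scan covers one coarse step on either side of the coarse optimum
#' in steps of `fine_step`.
#'
#' @param k ensemble size (default 200).
#' @param confinement_radius radius (reduced units) of the spherical
#'   confinement used during Brownian initialization; default `NULL`
#'   means one quarter of the chain contour length.
#' @param max_em_iter maximum EM iterations (default 20).
#' @param em_rel_tol relative ensemble-likelihood change declaring
#'   convergence (default 1e-4).
#' @param ascent_max_steps cap on gradient-ascent iterations per structure
#'   (default 2000).
#' @param ascent_tol projected-gradient threshold stopping the ascent
#'   (default 1e-3).
#' @param alpha_grid list `lo`, `hi`, `coarse_step`, `fine_step` for the
#'   conversion exponent (default 0.1..1.5, 10 coarse points).
#' @param sigma_grid same structure for \eqn{1/(2\sigma^2)}
#'   (default 0.1..10, 10 coarse points).
#' @param seed RNG seed making the whole run reproducible.
#' @param brownian_steps,brownian_dt,brownian_gamma,brownian_max_disp
#'   Langevin integration settings: step count (default 50000), time step
#'   (1e-4), friction (1), per-bead displacement cap (0.1 reduced units).
#' @return An object of class `inference_config`.
#' @export
inference_config <- function(k = 200, confinement_radius = NULL,
                             max_em_iter = 20, em_rel_tol = 1e-4,
                             ascent_max_steps = 2000, ascent_tol = 1e-3,
                             alpha_grid = list(lo = 0.1, hi = 1.5),
                             sigma_grid = list(lo = 0.1, hi = 10),
                             seed = 1L,
                             brownian_steps = 50000, brownian_dt = 1e-4,
                             brownian_gamma = 1, brownian_max_disp = 0.1) {
  fill_grid <- function(g) {
    if (is.null(g$coarse_step)) g$coarse_step <- (g$hi - g$lo) / 9
    if (is.null(g$fine_step)) g$fine_step <- 2 * g$coarse_step / 9
    if (g$hi <= g$lo || g$coarse_step <= 0 || g$fine_step <= 0)
      stop("grid must have hi > lo and positive steps")
    g
  }
  cfg <- list(k = as.integer(k), confinement_radius = confinement_radius,
              max_em_iter = as.integer(max_em_iter),
              em_rel_tol = em_rel_tol,
              ascent_max_steps = as.integer(ascent_max_steps),
              ascent_tol = ascent_tol,
              alpha_grid = fill_grid(alpha_grid),
              sigma_grid = fill_grid(sigma_grid),
              seed = as.integer(seed),
              brownian_steps = as.integer(brownian_steps),
              brownian_dt = brownian_dt, brownian_gamma = brownian_gamma,
              brownian_max_disp = brownian_max_disp)
  if (cfg$k < 1L) stop("ensemble size k must be at least 1")
  if (cfg$max_em_iter < 1L) stop("max_em_iter must be at least 1")
  with(cfg, stopifnot(em_rel_tol > 0, ascent_tol > 0,
                      brownian_steps > 0, brownian_dt > 0,
                      brownian_gamma > 0, brownian_max_disp > 0))
  structure(cfg, class = "inference_config")
}

confinement_radius_of <- function(model, cfg) {
  if (!is.null(cfg$confinement_radius)) cfg$confinement_radius
  else sum(model$rest_lengths) / 4
}

# Self-avoiding-ish random walk with steps equal to the rest lengths,
# confined to a sphere of the given radius about the origin.
random_walk_chain <- function(model, radius) {
  np <- model$n + 1L
  x <- matrix(0, np, 3L)
  for (i in seq_len(model$n)) {
    for (try in 1:100) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      cand <- x[i, ] + model$rest_lengths[i] * u
      if (sqrt(sum(cand^2)) <= radius) break
    }
    r <- sqrt(sum(cand^2))
    if (r > radius) cand <- cand * (0.95 * radius / r)
    x[i + 1L, ] <- cand
  }
  x
}

#' Generate an initial conformation pool by Brownian simulation
#'
#' Each member starts as a random walk with step lengths equal to the
#' segment rest lengths and is then relaxed by overdamped Langevin
#' dynamics on the conformational energy,
#' \eqn{s \leftarrow s - (dt/\gamma)\nabla E + \sqrt{2 k_B T\, dt/\gamma}\,\xi},
#' confined to a sphere (reflection at the boundary) whose radius stands
#' in for the physical size of the chromosome territory. Deterministic
#' given a seed.
#'
#' @param model a [segment_model()].
#' @param eparams an [energy_params()] object.
#' @param cfg an [inference_config()]; uses `k`, the `brownian_*` fields
#'   and `confinement_radius`.
#' @param seed optional seed; `NULL` continues from the current RNG state.
#' @return List of `k` conformation matrices with finite energy.
#' @export
brownian_initialize <- function(model, eparams = energy_params(), cfg,
                                seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  radius <- confinement_radius_of(model, cfg)
  out <- vector("list", cfg$k)
  for (i in seq_len(cfg$k)) {
    for (attempt in 1:5) {
      x0 <- random_walk_chain(model, radius)
      x <- brownian_cpp(x0, model$rest_lengths, eparams$k_s,
                        eparams$k_theta, eparams$epsilon, eparams$delta,
                        eparams$kBT, radius, cfg$brownian_steps,
                        cfg$brownian_dt, cfg$brownian_gamma,
                        cfg$brownian_max_disp)
      e <- sum(unlist(energy_terms_cpp(x, model$rest_lengths, eparams$k_s,
                                       eparams$k_theta, eparams$epsilon,
                                       eparams$delta)))
      if (is.finite(e)) break
    }
    if (!is.finite(e))
      stop("Brownian initialization failed to produce a finite-energy ",
           "member after 5 attempts")
    out[[i]] <- x
  }
  out
}

#' Refine one structure by gradient ascent on its log-posterior
#'
#' Maximizes the coordinate-dependent part of [log_posterior()],
#' \eqn{-E_S/k_BT - (1/2\sigma^2)\sum_i (D_i^S - D_i)^2}, by
#' limited-memory quasi-Newton gradient ascent (L-BFGS-B) with the
#' analytic gradient. Plain steepest ascent needs orders of magnitude
#' more iterations here because the spring constant (500 kBT per squared
#' length unit) makes the posterior extremely ill-conditioned relative to
#' the data term. The ascent stops when the projected gradient falls
#' below `ascent_tol` or after `ascent_max_steps` iterations, and the
#' result is guaranteed not to score below the input. Degenerate starting
#' geometry (infinite energy) is jittered by 1e-6 and retried.
#'
#' @inheritParams log_posterior
#' @param cfg an [inference_config()].
#' @return The refined conformation matrix, with attributes `objective`
#'   (final coordinate-dependent log-posterior part), `steps` (gradient
#'   evaluations used) and `converged`.
#' @export
optimize_structure <- function(coords, model, restraints,
                               eparams = energy_params(), nuisance, cfg) {
  stopifnot(inherits(nuisance, "nuisance_params"))
  coords <- as_conformation(coords, model)
  restraints <- restraint_targets(restraints, nuisance$alpha)
  pi0 <- as.integer(restraints$i) - 1L
  pj0 <- as.integer(restraints$j) - 1L
  half_w <- 1 / (2 * nuisance$sigma^2)
  negobj <- function(v) {
    x <- matrix(v, ncol = 3L)
    e <- energy_terms_cpp(x, model$rest_lengths, eparams$k_s,
                          eparams$k_theta, eparams$epsilon, eparams$delta)
    etot <- e$stretch + e$bend + e$exclude
    if (is.na(etot) || !is.finite(etot)) return(1e10)
    ds <- backcompute_cpp(x, pi0, pj0)
    etot / eparams$kBT + half_w * sum((ds - restraints$D)^2)
  }
  neggrad <- function(v) {
    x <- matrix(v, ncol = 3L)
    g <- tryCatch(
      energy_gradient_cpp(x, model$rest_lengths, eparams$k_s,
                          eparams$k_theta, eparams$epsilon,
                          eparams$delta) / eparams$kBT -
        data_gradient_cpp(x, pi0, pj0, restraints$D, nuisance$sigma),
      error = function(e) matrix(0, nrow(x), 3L))
    as.numeric(g)
  }
  for (attempt in 1:5) {
    f0 <- negobj(as.numeric(coords))
    if (f0 < 1e10) break
    coords <- coords + matrix(rnorm(length(coords), sd = 1e-6),
                              nrow(coords), 3L)
  }
  if (f0 >= 1e10)
    stop("structure optimization failed: persistent degenerate geometry")
  o <- stats::optim(as.numeric(coords), negobj, neggrad,
                    method = "L-BFGS-B",
                    control = list(maxit = cfg$ascent_max_steps,
                                   pgtol = cfg$ascent_tol, factr = 1e7))
  if (o$value <= f0) {
    out <- matrix(o$par, ncol = 3L)
    obj <- -o$value
  } else {                       # never return a worse structure
    out <- coords
    obj <- -f0
  }
  structure(out, objective = obj, steps = unname(o$counts[2L]),
            converged = o$convergence == 0L)
}

#' E step: refine and re-weight every ensemble member
#'
#' Optimizes each conformation independently at the current nuisance
#' parameters, recomputes the per-structure log-posteriors and renormalizes
#' the weights with [compute_weights()].
#'
#' @param ensemble an [ensemble_state()].
#' @inheritParams optimize_structure
#' @return The updated `ensemble_state`.
#' @export
e_step <- function(ensemble, model, restraints, eparams = energy_params(),
                   nuisance, cfg) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  confs <- lapply(ensemble$conformations, function(x) {
    y <- optimize_structure(x, model, restraints, eparams, nuisance, cfg)
    attributes(y) <- attributes(y)["dim"]
    y
  })
  ll <- vapply(confs, log_posterior, numeric(1), model = model,
               restraints = restraints, eparams = eparams,
               nuisance = nuisance)
  ensemble_state(confs, compute_weights(ll), ll)
}

#' M step: grid search over the nuisance parameters
#'
#' Scans a coarse grid over the conversion exponent \eqn{\alpha} and the
#' data weight \eqn{1/(2\sigma^2)}, then a fine grid bracketing the
#' coarse optimum, and returns the pair maximizing the ensemble
#' likelihood \eqn{\sum_i L(S_i \mid \alpha, \sigma, D) w_i} with the
#' weights held fixed from the preceding E step. Restraint targets are
#' re-converted per candidate \eqn{\alpha}. Exact ties break toward
#' smaller \eqn{\alpha}, then smaller \eqn{\sigma}.
#'
#' By default (`refit = TRUE`) the ensemble structures are re-optimized
#' (warm-started) for every candidate exponent before scoring it. This is
#' essential: structures fitted to the incumbent's targets make every
#' fixed-structure scan score the incumbent best (the scan then measures
#' only how far the candidate targets sit from the incumbent targets), so
#' without refitting the exponent can never move. `refit = FALSE` gives
#' the cheap fixed-structure scan over both axes.
#'
#' @param ensemble an [ensemble_state()] with weights from the preceding
#'   E step.
#' @inheritParams optimize_structure
#' @param incumbent optional [nuisance_params()] added to the candidate
#'   set, guaranteeing a monotone M step; its `sigma` also serves as the
#'   warm-start noise level for candidate refits.
#' @param calibration optional list `ref` (reference adjacent-pair
#'   distance) and `f_adj` (adjacent-pair frequencies): when supplied, the
#'   conversion scale is re-derived per candidate exponent as
#'   \eqn{\beta(\alpha) = ref / \mathrm{mean}(F_{adj}^{-\alpha})}, keeping
#'   the adjacent-pair anchor consistent across the whole scan; otherwise
#'   the restraint set's fixed `beta` attribute is used.
#' @param refit re-optimize the structures per candidate exponent
#'   (default `TRUE`).
#' @return A [nuisance_params()] with attributes `objective` (the ensemble
#'   likelihood at the optimum), `beta` (the scale at the returned
#'   exponent) and, when `refit = TRUE`, `conformations` (the members
#'   re-optimized at the winning exponent).
#' @export
m_step <- function(ensemble, model, restraints, eparams = energy_params(),
                   cfg, incumbent = NULL, calibration = NULL, refit = TRUE) {
  stopifnot(inherits(ensemble, "ensemble_state"))
  beta_of <- if (is.null(calibration)) {
    beta_fixed <- attr(restraints, "beta")
    function(alpha) beta_fixed
  } else {
    function(alpha) calibration$ref / mean(calibration$f_adj^(-alpha))
  }
  m <- nrow(restraints)
  wts <- ensemble$weights
  ag <- cfg$alpha_grid
  sg <- cfg$sigma_grid
  grid_seq <- function(g) seq(g$lo, g$hi, by = g$coarse_step)
  fine_seq <- function(g, best) {
    seq(max(g$lo, best - g$coarse_step), min(g$hi, best + g$coarse_step),
        by = g$fine_step)
  }
  sigma_warm <- if (!is.null(incumbent)) incumbent$sigma
                else sqrt(1 / (2 * mean(c(sg$lo, sg$hi))))

  # Score one exponent: (optionally) refit the members against its
  # targets, then grid-search the data weight with the fits held fixed
  # (the weight enters the likelihood analytically, so no refit per
  # weight is needed).
  eval_alpha <- function(alpha) {
    rs_a <- restraints
    attr(rs_a, "beta") <- beta_of(alpha)
    rs_a <- restraint_targets(rs_a, alpha)
    confs <- if (refit) {
      nu_a <- nuisance_params(alpha, sigma_warm)
      lapply(ensemble$conformations, function(x) {
        y <- optimize_structure(x, model, rs_a, eparams, nu_a, cfg)
        attributes(y) <- attributes(y)["dim"]
        y
      })
    } else ensemble$conformations
    Ds <- matrix(vapply(confs, back_compute_distances, numeric(m),
                        model = model, restraints = rs_a), nrow = m)
    ss <- colSums((Ds - rs_a$D)^2)
    Es <- vapply(confs, total_energy, numeric(1), model = model,
                 params = eparams) / eparams$kBT
    obj_w <- function(wfac) {
      sigma <- sqrt(1 / (2 * wfac))
      sum(wts * (-(m + 1) * log(sigma) - log(alpha) - Es - wfac * ss))
    }
    wc <- grid_seq(sg)
    ow <- vapply(wc, obj_w, numeric(1))
    wf <- fine_seq(sg, wc[which.max(ow)])
    of <- vapply(wf, obj_w, numeric(1))
    ws <- c(wc, wf)
    os <- c(ow, of)
    ord <- order(-ws)                    # ties toward smaller sigma
    best <- ord[which.max(os[ord])]
    list(alpha = alpha, wfac = ws[best], obj = os[best], confs = confs)
  }
  pick <- function(cands) {
    a <- vapply(cands, `[[`, numeric(1), "alpha")
    o <- vapply(cands, `[[`, numeric(1), "obj")
    ord <- order(a)                      # ties toward smaller alpha
    cands[[ord[which.max(o[ord])]]]
  }
  coarse <- lapply(grid_seq(ag), eval_alpha)
  b <- pick(coarse)
  fine <- lapply(setdiff(fine_seq(ag, b$alpha), grid_seq(ag)), eval_alpha)
  cands <- c(coarse, fine)
  if (!is.null(incumbent) &&
      !any(abs(vapply(cands, `[[`, numeric(1), "alpha") -
               incumbent$alpha) < 1e-12))
    cands <- c(cands, list(eval_alpha(incumbent$alpha)))
  b <- pick(cands)
  out <- nuisance_params(b$alpha, sqrt(1 / (2 * b$wfac)))
  attr(out, "objective") <- b$obj
  attr(out, "beta") <- beta_of(b$alpha)
  if (refit) attr(out, "conformations") <- b$confs
  out
}

#' Run the full EM ensemble inference
#'
#' End-to-end algorithm: draw initial \eqn{(\alpha, \sigma)} uniformly
#' over the grid bounds, calibrate \eqn{\beta} from sequence-adjacent
#' pairs, build the conformation pool by Brownian simulation, then
#' alternate [e_step()] and [m_step()] until the relative change of the
#' ensemble likelihood falls below `em_rel_tol` or `max_em_iter` is
#' reached. Fully reproducible given `config$seed`.
#'
#' @param fm a [frequency_matrix()].
#' @param fragment_table a fragment-table path, data frame, or
#'   [segment_model()].
#' @param config an [inference_config()].
#' @param eparams an [energy_params()] object.
#' @param min_freq frequency threshold below which pairs yield no
#'   restraint (default 0).
#' @param restraint_subset optional integer vector of restraint-record
#'   indices to keep (used by cross-validation to train on a subset).
#' @return An object of class `em_fit`: list with `ensemble`
#'   (an [ensemble_state()]), `nuisance` (fitted \eqn{\alpha, \sigma}),
#'   `beta`, `trace` (data frame with one row per EM iteration: ensemble
#'   likelihood, alpha, sigma, restraint correlation), `converged`,
#'   `iterations`, `model`, `restraints` and `config`.
#' @export
run_em <- function(fm, fragment_table, config = inference_config(),
                   eparams = energy_params(), min_freq = 0,
                   restraint_subset = NULL) {
  stopifnot(inherits(fm, "frequency_matrix"))
  model <- if (inherits(fragment_table, "segment_model")) fragment_table
           else build_segment_model(fragment_table, eparams)
  if (!is.null(config$seed)) set.seed(config$seed)

  ag <- config$alpha_grid; sg <- config$sigma_grid
  alpha0 <- runif(1, ag$lo, ag$hi)
  sigma0 <- sqrt(1 / (2 * runif(1, sg$lo, sg$hi)))

  pool <- brownian_initialize(model, eparams, config, seed = NULL)

  # Calibrate the conversion scale against the prior pool's own adjacent
  # midpoint distances: thermal bending makes midpoint separations of
  # adjacent fragments systematically shorter than the rest lengths, and
  # the pool is an unbiased sample of that equilibrium geometry.
  adj <- data.frame(i = seq_len(model$n - 1L), j = seq(2L, model$n))
  pool_adj <- mean(vapply(pool, function(x)
    mean(backcompute_cpp(x, adj$i - 1L, adj$j - 1L)), numeric(1)))
  ai <- seq_len(fm$n - 1L)
  f_adj <- fm$values[cbind(ai, ai + 1L)]
  f_adj <- f_adj[f_adj > 0]
  calib <- list(ref = pool_adj, f_adj = f_adj)
  beta <- calibrate_beta(fm, model, alpha0, reference_length = pool_adj)
  restraints <- convert_frequencies(
    fm, conversion_params(alpha0, beta, min_freq))
  if (!is.null(restraint_subset)) {
    restraints <- restraints[sort(unique(as.integer(restraint_subset))), ,
                             drop = FALSE]
    rownames(restraints) <- NULL
    attr(restraints, "alpha") <- alpha0
    attr(restraints, "beta") <- beta
    class(restraints) <- c("restraint_set", "data.frame")
    if (!nrow(restraints)) stop("restraint subset is empty")
  }

  ensemble <- ensemble_state(pool)
  nuisance <- nuisance_params(alpha0, sigma0)

  trace <- data.frame(iteration = integer(), ensemble_likelihood = numeric(),
                      alpha = numeric(), sigma = numeric(),
                      restraint_correlation = numeric())
  l_prev <- NA_real_
  converged <- FALSE
  iter <- 0L
  while (iter < config$max_em_iter) {
    iter <- iter + 1L
    ensemble <- e_step(ensemble, model, restraints, eparams, nuisance,
                       config)
    nuisance <- m_step(ensemble, model, restraints, eparams, config,
                       incumbent = nuisance, calibration = calib)
    beta <- attr(nuisance, "beta")
    attr(restraints, "beta") <- beta
    refit_confs <- attr(nuisance, "conformations")
    if (!is.null(refit_confs))        # keep the members refit at the winner
      ensemble <- ensemble_state(refit_confs, ensemble$weights,
                                 ensemble$log_likelihoods)
    # ensemble likelihood and diagnostics at the new parameters
    rs <- restraint_targets(restraints, nuisance$alpha)
    ll <- vapply(ensemble$conformations, log_posterior, numeric(1),
                 model = model, restraints = rs, eparams = eparams,
                 nuisance = nuisance)
    ensemble <- ensemble_state(ensemble$conformations, ensemble$weights, ll)
    l_ens <- ensemble_likelihood(ll, ensemble$weights)
    Ds <- vapply(ensemble$conformations, back_compute_distances,
                 numeric(nrow(rs)), model = model, restraints = rs)
    pred <- as.numeric(matrix(Ds, nrow = nrow(rs)) %*% ensemble$weights)
    rho <- if (stats::sd(pred) > 0 && stats::sd(rs$D) > 0)
      cor(pred, rs$D) else NA_real_
    trace <- rbind(trace, data.frame(
      iteration = iter, ensemble_likelihood = l_ens,
      alpha = nuisance$alpha, sigma = nuisance$sigma,
      restraint_correlation = rho))
    if (is.finite(l_prev) &&
        abs(l_ens - l_prev) / max(abs(l_ens), 1e-12) < config$em_rel_tol) {
      converged <- TRUE
      break
    }
    l_prev <- l_ens
  }
  if (!converged)
    warning("EM did not reach em_rel_tol within ", config$max_em_iter,
            " iterations")
  # final weights consistent with the final parameters
  ensemble <- ensemble_state(ensemble$conformations,
                             compute_weights(ensemble$log_likelihoods),
                             ensemble$log_likelihoods)
  structure(list(ensemble = ensemble, nuisance = nuisance, beta = beta,
                 trace = trace, converged = converged, iterations = iter,
                 model = model,
                 restraints = restraint_targets(restraints, nuisance$alpha),
                 config = config),
            class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  cat(sprintf("EM ensemble fit: k = %d, %d restraints, %d iterations%s\n",
              length(x$ensemble$conformations), nrow(x$restraints),
              x$iterations,
              if (x$converged) " (converged)" else " (not converged)"))
  cat(sprintf("  alpha = %.4f, sigma = %.4f, beta = %.4f\n",
              x$nuisance$alpha, x$nuisance$sigma, x$beta))
  cat(sprintf("  ensemble likelihood = %.4f, restraint correlation = %.3f\n",
              x$trace$ensemble_likelihood[x$iterations],
              x$trace$restraint_correlation[x$iterations]))
  invisible(x)
}
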