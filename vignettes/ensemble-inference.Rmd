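---
title: "Ensemble inference of 3D chromatin structure from 3C contact frequencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble inference of 3D chromatin structure from 3C contact frequencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoem)
```

## The problem

Chromosome conformation capture (3C/Hi-C) experiments count ligation
events between pairs of genomic loci across a population of cells. At
restriction-fragment resolution the data form a symmetric matrix of
interaction frequencies $F_{ij}$. `chromoem` turns such a matrix into an
*ensemble* of 3D conformations of the chromosome, each with a weight,
together with estimates of two nuisance parameters: the exponent $\alpha$
of the frequency-to-distance conversion and the noise level $\sigma$ of
the distance restraints.

An ensemble rather than a single consensus structure is the appropriate
output because the counts are averaged over many heterogeneous cells and
because interphase chromosomes are intrinsically dynamic.

## The model

**Chain representation.** A chromosome is a linear chain of $n$
segments, one per restriction fragment; the $n+1$ segment end points
$s_1, \dots, s_{n+1}$ (the cut sites plus the two chromosome ends) carry
the 3D coordinates. For yeast chromosome 1 digested with HindIII this
gives 47 segments and 48 end points. Internally everything is in reduced
units: one length unit is 30 nm of fiber, one energy unit is $k_BT$.

**Conformational energy (the prior).** Three standard bead–spring
polymer terms, summed into $E_S$:

* *stretching*: $\sum_i \tfrac12 k_s (l_i - l_{i0})^2$ with
  $k_s = 500\,k_BT/\delta^2$; the rest length $l_{i0}$ comes from the
  fragment's base-pair count at a packing density of 130 bp/nm;
* *bending*: $\sum_i \tfrac12 k_\theta \theta_i^2$ with
  $k_\theta = 4\,k_BT/\mathrm{rad}^2$, $\theta_i$ the planar angle
  between consecutive bonds (the two-vector form; a dihedral would need
  three bonds and is deliberately out of scope);
* *excluded volume*: the purely repulsive truncated-and-shifted
  Lennard-Jones (WCA) potential with size $\delta = 1$ (30 nm) and depth
  $\epsilon = 1\,k_BT$, cut off at $2^{1/6}\delta$, summed over **all**
  end-point pairs including bonded neighbours and the terminal bead.
  Excluding the chain ends would leave them unprotected against
  collapse, and for bonded pairs the much stiffer spring dominates
  anyway.

The prior on a conformation is the Boltzmann weight
$\Pr(S) \propto e^{-E_S/k_BT}$.

**Likelihood.** Frequencies convert to target distances through
$D_i = \beta F_i^{-\alpha}$. Each restraint is anchored at the
*midpoints* of its two fragments (a ligation event localizes within the
fragment, and midpoints keep the restraint symmetric); the back-computed
distance $D_i^S$ is the Euclidean distance between those midpoints.
Residuals are Gaussian with standard deviation $\sigma$, and Jeffreys
priors on $\sigma$ and $\alpha$ give the per-structure log-posterior

$$
L(S \mid D, \sigma, \alpha) \;=\; -\log\sigma - \log\alpha
  - \frac{E_S}{k_BT}
  - \frac{1}{2\sigma^2}\sum_{i=1}^m \left(D_i^S - D_i\right)^2
  - m\log\sigma .
$$

$1/(2\sigma^2)$ doubles as the weighting factor between the data term
and the energy prior. Pairs with frequency at or below `min_freq`
(default 0) contribute **no** restraint: an unobserved contact is
censored, not evidence of a large distance.

**Ensemble.** The ensemble is $\{(S_i, w_i)\}_{i=1..k}$ with weights
$w_i = \exp(L_i - \operatorname{logsumexp} L)$ normalized in log space
(raw exponentials underflow at chromosome-scale $m$), and the *ensemble
likelihood* $L_{\mathrm{ens}} = \sum_i L_i w_i$ is the objective
monitored for convergence. The default $k = 200$ matches full-scale use;
the bundled tests use $k = 20$ so they finish in seconds per run.

## The EM algorithm

1. **Initialization.** $\alpha$ and $1/(2\sigma^2)$ are drawn uniformly
   over their grid bounds (seeded). A pool of $k$ conformations is
   generated by overdamped Langevin (Brownian) dynamics on $E_S$:
   $s \leftarrow s - (dt/\gamma)\nabla E + \sqrt{2k_BT\,dt/\gamma}\,\xi$,
   started from a random walk with rest-length steps and confined to a
   sphere standing in for the chromosome territory (default radius:
   one quarter of the contour length, configurable). Defaults
   $dt = 10^{-4}$, $\gamma = 1$, 50&nbsp;000 steps; per-bead
   displacements are capped at 0.1 reduced units per step because the
   $r^{-12}$ excluded-volume force is stiff enough to catapult beads on
   the rare close encounter.
2. **Scale calibration.** $\beta$ is anchored on sequence-adjacent
   pairs: the mean converted adjacent distance is matched to the mean
   adjacent *midpoint* distance of the Brownian pool. The pool-based
   reference (rather than the bare mean rest length, which
   `calibrate_beta()` uses by default) matters because thermal bending
   makes adjacent midpoint separations systematically $\sim$10% shorter
   than rest lengths. The anchor is re-applied per candidate $\alpha$
   inside the grid search, $\beta(\alpha) = \bar d_{\mathrm{adj}} /
   \operatorname{mean}(F_{\mathrm{adj}}^{-\alpha})$, so the scale stays
   consistent across the whole scan instead of inheriting whatever
   $\alpha$ the run happened to start from.
3. **E step.** Every member is refined by gradient ascent on its
   log-posterior and the weights are recomputed. The ascent is
   L-BFGS-B with the analytic gradient: with $k_s = 500$ the posterior
   is ill-conditioned by roughly three orders of magnitude, and plain
   steepest ascent measurably fails to converge within $10^4$
   iterations while the quasi-Newton ascent reaches the same optimum an
   independent long steepest-ascent run approaches, in about a hundred
   gradient evaluations. A member is never replaced by a worse one.
4. **M step.** A grid search over $\alpha \in [0.1, 1.5]$ and
   $1/(2\sigma^2) \in [0.1, 10]$ (10 coarse points per axis, then 10
   fine points across the bracketing coarse cells) maximizes
   $L_{\mathrm{ens}}$ with the weights held fixed. The grid bounds
   bracket the regime where chromosome-scale 3C analyses operate, with
   the conversion exponent below 1 and the data weight of order 1.
   Crucially, the ensemble members are
   **re-optimized (warm-started) for every candidate exponent** before
   it is scored. With members left fixed, the scan degenerates: since
   the structures were fitted to the incumbent's targets, every
   alternative exponent scores worse by construction and the
   parameters can never move — runs freeze at whatever exponent the
   first iteration happened to pick, with $\sigma$ stuck at a
   self-consistent loose-fit stationary point.
   The noise axis needs no refits per candidate
   because $\sigma$ enters the likelihood analytically once the
   residuals are known. Exact ties break toward smaller $\alpha$, then
   smaller $\sigma$; `m_step(refit = FALSE)` retains the cheap
   fixed-structure scan for diagnostic use.
5. **Convergence.** Steps 3–4 alternate until the relative change of
   $L_{\mathrm{ens}}$ falls below `em_rel_tol` (default $10^{-4}$) or
   `max_em_iter` (default 20) iterations. The restraint correlation is
   logged per iteration but not used for stopping. Every run is a pure
   function of its seed.

## The synthetic-data generator

`synthetic_spec()` defines the reference test instance: 20 fragments
with lengths drawn log-uniformly from 1–40 kb (the restriction-fragment
scale of a small yeast chromosome), true exponent $\alpha^* = 0.5$,
distance noise $\sigma^* = 0.1$ reduced units (3 nm), and a ground
*truth that is itself an ensemble* of `k_truth = 5` conformations drawn
from the Boltzmann distribution of the energy model. Frequencies are
obtained by inverting the conversion law on the noisy ensemble-mean
midpoint distances, $F = (D'/\beta^*)^{-1/\alpha^*}$, with the noise
truncated below at $0.05\bar D$ so distances stay positive. The true
scale $\beta^*$ defaults to the mean rest length, which keeps
adjacent-pair frequencies near 1. With `noise_sigma = 0` the
generate-then-convert loop is an exact inversion, which the tests
exploit.

What the generator does *not* emulate: sequencing-count statistics
(overdispersion, coverage bias), matrix-correction artifacts, trans
contacts, or genuinely multimodal conformational populations. Passing
tests therefore demonstrate the estimator's behaviour under its own
modelling assumptions, not robustness to real Hi-C pathologies.

## What the tests establish — and a known bias

On the reference instance ($k = 20$, seeded), the EM recovers
$\hat\alpha$ within $\pm 0.1$ of $\alpha^*$ with back-computed versus
target distance correlations above 0.98, the ensemble-likelihood trace
stabilizes (relative change $< 10^{-4}$) within a handful of
iterations, and 5-fold cross-validation on a noiseless instance attains
pooled predicted-versus-expected correlations around 0.97.

One bias is worth stating plainly. Across replicate instances the
exponent error is consistently *positive* (median around $+0.05$ to
$+0.07$, one to two fine-grid steps; the acceptance script and the test
suite both recompute it). Controlled comparisons localize the cause:
with a single ground-truth conformation the estimator is essentially
unbiased (the test suite checks recovery to within one fine-grid step
in that setting), while with ensemble-averaged distances the bias
appears even at zero noise and even with the conversion scale fixed at
its true value. Averaging over
conformations contracts the long-range entries of a distance matrix
relative to any realizable single structure, and a slightly larger
exponent re-expands the long-range targets into a more embeddable set —
so the per-structure Gaussian likelihood genuinely peaks above
$\alpha^*$. This is a property of fitting population-averaged
restraints with per-structure likelihoods, i.e. of the method itself,
and it is one more reason to read the fitted $\alpha$ as an effective
conversion parameter rather than a physical constant. Modelling the
averaging explicitly (scoring the ensemble-mean back-computed distance
against the data) would be the natural extension but is a different
likelihood than the one implemented here.

## Numerical choices

* Bend angles use $\arccos$ of the normalized dot product clamped to
  $[-1, 1]$; the gradient factor $\theta/\sin\theta$ is continued to 1
  at $\theta = 0$ and guarded at $\theta = \pi$.
* A coincident pair in the excluded-volume sum yields $+\infty$ energy
  (the optimizer rejects the state) rather than an exception; degenerate
  *starting* geometry is jittered by $10^{-6}$ and retried.
* The WCA form is $C^1$ at its cutoff, so analytic gradients match
  central finite differences ($h = 10^{-6}$) to better than $10^{-4}$
  everywhere the tests probe.
* Fragment indices are 1-based in files and at the R surface; genomic
  coordinates are 0-based half-open. Asymmetric input matrices are
  symmetrized by averaging with a warning.
* Structure files store nm; XYZ round-trips at $10^{-6}$ nm and the
  PDB CA-trace (nm written into the angstrom fields) at
  $5\times10^{-4}$ nm.
* Cross-validation folds are seeded, sizes differ by at most one, and
  test-set expected distances use the $\alpha$ fitted on the *training*
  folds only — using the test fold would leak.
* The distance-versus-separation trend is fitted with the saturating
  form $d(s) = d_{\max}(1 - e^{-s/s_0})$ (Levenberg–Marquardt via
  minpack.lm), chosen because confinement visibly saturates spatial
  distance at large genomic separation; the form is isolated in
  `fit_saturating_curve()` and easy to swap.

## Problem sizes used in the bundled checks

The shipped tests and the acceptance script run the 20-fragment
reference instance with $k = 20$ (about 190 restraints), ten recovery
replicates, and a 5-fold cross-validation at $k = 10$ — each EM run
takes tens of seconds. Full-scale analyses ($k = 200$, longer
chromosomes) use the same code paths; only `k`, the grids and the
Langevin settings are configuration.

## Known limitations

* The Gaussian likelihood is the only noise model; a count-based
  (Poisson) likelihood is out of scope.
* Restraint anchoring at fragment midpoints is a modelling choice; cut
  sites would be the alternative.
* Single chromosomes only: no trans contacts, no nucleus-shape prior
  beyond the initialization confinement sphere.
* The exponent bias under population-averaged input discussed above.
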