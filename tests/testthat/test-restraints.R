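test_that("square frequency matrices round-trip and reject malformed input", {
  p <- withr::local_tempfile(fileext = ".tsv")
  fm <- frequency_matrix(rbind(c(0, 4, 1), c(4, 0, 2), c(1, 2, 0)))
  write_frequency_matrix(fm, p)
  fm2 <- read_frequency_matrix(p, "square")
  expect_equal(fm2$values, fm$values)
  expect_equal(fm2$n, 3)

  set.seed(8)
  v <- matrix(runif(400), 20, 20)
  v <- v + t(v); diag(v) <- 0
  fm3 <- frequency_matrix(v)
  write_frequency_matrix(fm3, p)
  expect_equal(read_frequency_matrix(p, "square")$values, v)

  writeLines(c("\ta\tb", "a\t0\t1", "b\t1"), p)
  expect_error(read_frequency_matrix(p, "square"), "line 3")
  writeLines(c("\ta\tb", "a\t0\tx", "b\t1\t0"), p)
  expect_error(read_frequency_matrix(p, "square"), "non-numeric")
  writeLines(c("\ta\tb", "a\t0\t-1", "b\t-1\t0"), p)
  expect_error(read_frequency_matrix(p, "square"), "negative")
})

test_that("triplet dialect treats absent pairs as zero", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines("1\t2\t4.0", p)
  fm <- read_frequency_matrix(p, "triplet", n_fragments = 3)
  expect_equal(fm$values[1, 2], 4)
  expect_equal(fm$values[1, 3], 0)
  expect_equal(fm$values[2, 3], 0)
  writeLines(c("1\t2\t4.0", "2\tx\t1"), p)
  expect_error(read_frequency_matrix(p, "triplet"), "line 2")
})

test_that("asymmetric input is symmetrized with a warning", {
  v <- rbind(c(0, 1, 0), c(3, 0, 0), c(0, 0, 0))
  expect_warning(fm <- frequency_matrix(v), "symmetriz")
  expect_equal(fm$values[1, 2], 2)
  expect_equal(fm$values[2, 1], 2)
})

test_that("fragment tables build chain models", {
  p <- withr::local_tempfile(fileext = ".tsv")
  # a 47-fragment chromosome: 46 internal cut sites, 48 end points
  ends <- cumsum(rep(5000, 47))
  write.table(data.frame("chr1", c(0, ends[-47]), ends), p, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  m <- build_segment_model(p)
  expect_equal(m$n, 47)
  expect_equal(m$n + 1, 48)

  # single fragment of 3900 bp at 130 bp/nm and 30 nm/unit: rest length 1
  m2 <- segment_model(cbind(c(0, 3900), c(3900, 7800)))
  expect_equal(m2$rest_lengths[1], 1.0)

  # conservation: bp lengths sum to the spanned extent
  set.seed(9)
  bp <- sample(1000:40000, 12)
  ends <- cumsum(bp)
  write.table(data.frame("chr2", c(0, ends[-12]), ends), p, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  m3 <- build_segment_model(p)
  expect_equal(sum(m3$bp_lengths), ends[12])

  write.table(data.frame("chr2", c(0, 6000), c(5000, 11000)), p,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  expect_error(build_segment_model(p), "row 1")
})

test_that("frequency-to-distance conversion follows the power law", {
  fm <- frequency_matrix(rbind(c(0, 1, 4), c(1, 0, 9), c(4, 9, 0)))
  rs <- convert_frequencies(fm, conversion_params(alpha = 0.5, beta = 2))
  expect_equal(rs$D[rs$i == 1 & rs$j == 2], 2)        # F = 1 -> D = beta
  expect_equal(rs$D[rs$i == 1 & rs$j == 3], 2 / 2)    # F = 4, alpha = 1/2
  # degenerate exponent: all targets collapse to beta
  rs0 <- convert_frequencies(fm, conversion_params(alpha = 0, beta = 3))
  expect_true(all(rs0$D == 3))
  # strict monotone decrease in F for alpha > 0
  f <- sort(runif(50, 0.1, 20))
  d <- 1.5 * f^(-0.7)
  expect_true(all(diff(d) < 0))
  # thresholding: pairs at or below min_freq yield no restraint
  rs2 <- convert_frequencies(fm, conversion_params(0.5, 1, min_freq = 1))
  expect_equal(nrow(rs2), 2)
  expect_error(convert_frequencies(fm, conversion_params(0.5, 1, 100)),
               "no fragment pair")
})

test_that("beta calibration inverts the adjacent-pair construction", {
  m <- test_model(4, rest = 1.2)
  fm <- frequency_matrix(matrix(1, 4, 4) - diag(4))
  expect_equal(calibrate_beta(fm, m, alpha = 0.7), 1.2)

  # synthetic matrix built from a known beta with noiseless adjacent
  # frequencies equal to rest-length distances
  beta_true <- 0.8
  d_adj <- c(1.0, 1.4, 1.2)
  f_adj <- (d_adj / beta_true)^(-1 / 0.5)
  v <- matrix(0, 4, 4)
  v[cbind(1:3, 2:4)] <- f_adj; v[cbind(2:4, 1:3)] <- f_adj
  fm2 <- frequency_matrix(v)
  ends <- cumsum(rep(3900, 4))
  m2 <- segment_model(cbind(c(0, ends[-4]), ends))
  expect_equal(calibrate_beta(fm2, m2, 0.5,
                              reference_length = mean(d_adj)),
               beta_true, tolerance = 1e-9)

  # scale equivariance: doubling all frequencies at alpha = 0.5
  expect_equal(calibrate_beta(frequency_matrix(2 * v), m2, 0.5),
               sqrt(2) * calibrate_beta(fm2, m2, 0.5))
})

test_that("structure files round-trip in both formats", {
  set.seed(10)
  x <- matrix(rnorm(48 * 3, sd = 3), 48, 3)
  for (fmt in c("xyz", "pdb")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_structure(x, energy_params(), p, fmt)
    y <- read_structure(p)
    expect_lt(max(abs(y - x)) * 30, 1e-3)   # 1e-3 nm
  }
  # pdb has exactly n+1 atom records
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(x, energy_params(), p, "pdb")
  expect_equal(sum(grepl("^ATOM", readLines(p))), 48)
  expect_error(read_structure(file.path(tempdir(), "absent.xyz")),
               "not found")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("3", "c", "C 1 2 3"), bad)
  expect_error(read_structure(bad), "truncated")
})

test_that("pdb output is readable by an independent parser", {
  skip_if_not_installed("bio3d")
  set.seed(11)
  x <- matrix(rnorm(15, sd = 2), 5, 3)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_structure(x, energy_params(), p, "pdb")
  pdb <- bio3d::read.pdb(p)
  xyz <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  expect_equal(xyz / 30, x, tolerance = 1e-3)
})

test_that("ensembles round-trip with consistent weights", {
  set.seed(12)
  confs <- replicate(5, matrix(rnorm(18), 6, 3), simplify = FALSE)
  ll <- rnorm(5)
  ens <- ensemble_state(confs, compute_weights(ll), ll)
  d <- withr::local_tempdir()
  write_ensemble(ens, d)
  ens2 <- read_ensemble(d)
  expect_equal(ens2$weights, ens$weights)
  expect_equal(ens2$log_likelihoods, ens$log_likelihoods)
  expect_equal(ens2$conformations[[3]], ens$conformations[[3]],
               tolerance = 1e-4)

  # weights that do not sum to 1 are a consistency error
  wt <- read.table(file.path(d, "weights.tsv"), header = TRUE, sep = "\t")
  wt$weight <- wt$weight * 0.8
  write.table(wt, file.path(d, "weights.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_ensemble(d), "sum to")
  # missing weight row
  wt <- wt[-2, ]; wt$weight <- wt$weight / sum(wt$weight)
  write.table(wt, file.path(d, "weights.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(read_ensemble(d), "4 rows|missing")
  expect_error(read_ensemble(withr::local_tempdir()), "no structure")
})
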