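test_that("the unbiased single-window limit equals histogram inversion", {
  set.seed(6)
  z <- runif(4000, -3, 3)
  # vanishing force constant: bias factors are 1 everywhere
  w <- umbrella_window(0, 1e-6, z)
  pmf <- solve_wham(list(w), bin_width = 0.5, temperature_K = 310)
  kT <- thermal_energy(310)
  edges <- c(pmf$z_centers - 0.25, max(pmf$z_centers) + 0.25)
  h <- tabulate(findInterval(z, edges, rightmost.closed = TRUE),
                nbins = length(pmf$z_centers))
  G_ref <- -kT * log(h / sum(h))
  G_ref <- G_ref - min(G_ref)
  expect_equal(pmf$G, G_ref, tolerance = 1e-6)
  # and a uniform sample is flat within binning noise
  expect_lt(max(pmf$G, na.rm = TRUE), 0.5)
})

test_that("a flat potential is recovered flat within the sampling noise", {
  # The window free energies perform a random walk with per-step SD about
  # k * sigma/sqrt(n) * spacing; at 36 windows x 2000 samples the expected
  # min-to-max spread of G is ~1.4 kJ/mol, so 3 kJ/mol is a generous
  # deterministic envelope at this fixed seed.
  win <- sample_umbrella_windows(flat_truth(), seq(-17.5, 17.5, 1), 1000,
                                 n_samples = 2000, seed = 19)
  pmf <- solve_wham(win, bin_width = 0.2, temperature_K = 310)
  expect_true(pmf$converged)
  expect_lt(max(abs(pmf$G), na.rm = TRUE), 3)
})

test_that("a double-Gaussian barrier is recovered near its true height", {
  dg <- function(z) 15 * exp(-(z - 3)^2 / 8) + 15 * exp(-(z + 3)^2 / 8)
  truth <- ground_truth_profile(dg, temperature_K = 310)
  win <- sample_umbrella_windows(truth, seq(-17.5, 17.5, 1), 1000,
                                 n_samples = 3000, seed = 23)
  pmf <- solve_wham(win, bin_width = 0.2, temperature_K = 310)
  peak_true <- max(dg(seq(-18, 18, 0.01)))
  expect_lt(abs(max(pmf$G, na.rm = TRUE) - peak_true), 1.5)
  # peak positions near +-3 A
  ok <- !is.na(pmf$G)
  z_at_max <- pmf$z_centers[ok][which.max(pmf$G[ok])]
  expect_lt(min(abs(z_at_max - c(-3, 3))), 1)
})

test_that("a harmonic well's curvature is recovered through WHAM", {
  kappa <- 10   # kJ/mol/A^2
  kT <- thermal_energy(310)
  truth <- ground_truth_profile(function(z) 0.5 * kappa * z^2,
                                temperature_K = 310)
  win <- sample_umbrella_windows(truth, 0, force_constant = 1000,
                                 n_samples = 10000, seed = 29)
  # biased variance is kT/(kappa + k)
  expect_equal(sd(win[[1]]$samples), sqrt(kT / (kappa + 10)), tolerance = 0.03)
  pmf <- solve_wham(win, bin_width = 0.05, temperature_K = 310)
  ok <- !is.na(pmf$G) & abs(pmf$z_centers) < 0.5
  fit <- lm(pmf$G[ok] ~ poly(pmf$z_centers[ok], 2, raw = TRUE))
  kappa_hat <- 2 * coef(fit)[3]
  expect_lt(abs(kappa_hat - kappa) / kappa, 0.15)
})

test_that("WHAM is deterministic and flags non-overlapping windows", {
  win <- sample_umbrella_windows(flat_truth(), c(-2, -1, 0, 1, 2), 1000,
                                 n_samples = 500, seed = 31)
  p1 <- solve_wham(win, bin_width = 0.2)
  p2 <- solve_wham(win, bin_width = 0.2)
  expect_identical(p1$G, p2$G)
  far <- sample_umbrella_windows(flat_truth(), c(-30, 30), 1000,
                                 n_samples = 200, seed = 37)
  expect_warning(pf <- solve_wham(far, bin_width = 0.2), "share no occupied")
  expect_false(pf$converged)
  expect_error(solve_wham(list()), "no umbrella windows")
})

test_that("forced identical bootstrap weights give zero stderr", {
  win <- sample_umbrella_windows(flat_truth(), c(-2, -1, 0, 1, 2), 1000,
                                 n_samples = 500, seed = 41)
  pmf <- bootstrap_pmf(win, bin_width = 0.2, n_boot = 2, seed = 1,
                       weight_sampler = function(n) rep(1, n))
  expect_true(all(pmf$stderr[!is.na(pmf$stderr)] == 0))
})

test_that("bootstrap bands cover a flat truth at most bins", {
  win <- sample_umbrella_windows(flat_truth(), seq(-5.5, 5.5, 1), 1000,
                                 n_samples = 1000, seed = 43)
  pmf <- bootstrap_pmf(win, bin_width = 0.2, n_boot = 50, seed = 7)
  ok <- !is.na(pmf$G) & !is.na(pmf$stderr)
  # the flat truth is a constant; compare against the stderr-weighted level
  level <- sum(pmf$G[ok] / pmf$stderr[ok]^2) / sum(1 / pmf$stderr[ok]^2)
  covered <- abs(pmf$G[ok] - level) <= 2 * pmf$stderr[ok]
  expect_gte(mean(covered), 0.9)
})

test_that("bootstrap stderr shrinks roughly as one over sqrt(n)", {
  mk <- function(n) sample_umbrella_windows(flat_truth(), seq(-3.5, 3.5, 1),
                                            1000, n_samples = n, seed = 47)
  p1 <- bootstrap_pmf(mk(500), bin_width = 0.2, n_boot = 40, seed = 3)
  p2 <- bootstrap_pmf(mk(2000), bin_width = 0.2, n_boot = 40, seed = 3)
  ratio <- mean(p2$stderr, na.rm = TRUE) / mean(p1$stderr, na.rm = TRUE)
  expect_gt(ratio, 0.35)
  expect_lt(ratio, 0.75)
})

test_that("bootstrap replicates are reproducible by seed", {
  win <- sample_umbrella_windows(flat_truth(), c(-1, 0, 1), 1000,
                                 n_samples = 400, seed = 53)
  p1 <- bootstrap_pmf(win, bin_width = 0.2, n_boot = 10, seed = 5)
  p2 <- bootstrap_pmf(win, bin_width = 0.2, n_boot = 10, seed = 5)
  expect_identical(p1$stderr, p2$stderr)
  p3 <- bootstrap_pmf(win, bin_width = 0.2, n_boot = 10, seed = 6)
  expect_false(identical(p1$stderr, p3$stderr))
})

test_that("stationary windows pass the consecutive-fraction check", {
  win <- sample_umbrella_windows(flat_truth(), seq(-8.5, 8.5, 1), 1000,
                                 n_samples = 4000, seed = 59)
  conv <- convergence_by_fractions(win, n_fractions = 2, bin_width = 0.2)
  expect_true(conv$stationary)
  expect_lt(conv$max_discrepancy_kJmol, 1.5)
  expect_error(convergence_by_fractions(win, n_fractions = 1), ">= 2")
})

test_that("a constructed drift is detected by the fraction check", {
  win <- sample_umbrella_windows(flat_truth(), seq(-8.5, 8.5, 1), 1000,
                                 n_samples = 2000, seed = 61)
  drifted <- lapply(win, function(w) {
    half <- seq_along(w$samples) > length(w$samples) / 2
    w$samples[half] <- w$samples[half] + 5
    w
  })
  conv <- suppressWarnings(
    convergence_by_fractions(drifted, n_fractions = 2, bin_width = 0.2))
  expect_gt(conv$max_discrepancy_kJmol, 2)
})
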