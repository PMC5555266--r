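# Minimal density_profile construction via the public counting path.
dens_from_avg <- function(n_norm, frames_used = 100) {
  nb <- length(n_norm)
  structure(list(z_centers = seq_len(nb) - 0.5,
                 per_frame = matrix(n_norm, nrow = 1),
                 average = n_norm,
                 undefined = rep(FALSE, nb), area = rep(1, nb),
                 bin_width = 1, n_bulk = 0.0334,
                 frames_used = frames_used, frame_times = 0),
            class = "density_profile")
}

test_that("thermal energy matches k_B T at reference temperatures", {
  expect_equal(round(thermal_energy(310), 3), 2.577)
  expect_equal(round(thermal_energy(310), 1), 2.6)
  expect_equal(thermal_energy(1 / 0.0083144621), 1.0)
  expect_error(thermal_energy(0), "positive")
  expect_error(thermal_energy(-5), "positive")
})

test_that("uniform density inverts to zero free energy everywhere", {
  d <- dens_from_avg(rep(1, 10))
  fep <- boltzmann_invert(d, 310, bulk_bins = 1:3)
  expect_equal(fep$E, rep(0, 10))
  expect_false(any(fep$censored))
})

test_that("half-bulk density gives kT ln 2", {
  d <- dens_from_avg(c(1, 1, 0.5, 1))
  fep <- boltzmann_invert(d, 310, bulk_bins = c(1, 2, 4))
  kT <- thermal_energy(310)
  expect_equal(fep$E[3], kT * log(2), tolerance = 1e-12)
  expect_equal(fep$E[3], 1.7866, tolerance = 1e-4)
})

test_that("exact inversion round trip recovers any tabulated profile", {
  kT <- thermal_energy(310)
  set.seed(4)
  for (rep in 1:5) {
    E_star <- c(0, 0, abs(rnorm(8, 5, 4)), 0, 0)
    n <- exp(-E_star / kT)
    fep <- boltzmann_invert(dens_from_avg(n), 310,
                            bulk_bins = c(1, 2, 11, 12))
    expect_lt(max(abs(fep$E - E_star)), 1e-9)
  }
})

test_that("free energy scales proportionally with temperature", {
  n <- c(1, 1, 0.3, 0.1, 1, 1)
  f1 <- boltzmann_invert(dens_from_avg(n), 310, bulk_bins = c(1, 2, 5, 6))
  f2 <- boltzmann_invert(dens_from_avg(n), 620, bulk_bins = c(1, 2, 5, 6))
  expect_equal(f2$E, 2 * f1$E, tolerance = 1e-12)
})

test_that("the additive constant cancels for rescaled densities", {
  n <- c(1, 1, 0.4, 0.2, 1, 1)
  f1 <- boltzmann_invert(dens_from_avg(n), 310, bulk_bins = c(1, 2, 5, 6))
  f2 <- boltzmann_invert(dens_from_avg(3.7 * n), 310, bulk_bins = c(1, 2, 5, 6))
  expect_equal(f2$E, f1$E, tolerance = 1e-12)
})

test_that("zero-density bins are capped and flagged, or censored to NA", {
  d <- dens_from_avg(c(1, 1, 0, 1), frames_used = 99)
  kT <- thermal_energy(310)
  fep <- boltzmann_invert(d, 310, bulk_bins = c(1, 2, 4))
  expect_true(fep$censored[3])
  expect_equal(fep$E[3], -kT * log(1 / 100), tolerance = 1e-12)
  cen <- boltzmann_invert(d, 310, bulk_bins = c(1, 2, 4),
                          zero_handling = "censor-only")
  expect_true(is.na(cen$E[3]))
  expect_true(cen$censored[3])
  # more frames can only raise the cap
  d2 <- dens_from_avg(c(1, 1, 0, 1), frames_used = 999)
  fep2 <- boltzmann_invert(d2, 310, bulk_bins = c(1, 2, 4))
  expect_gt(fep2$E_cap, fep$E_cap)
})

test_that("inversion refuses a zero-density bulk anchor", {
  d <- dens_from_avg(c(0, 0, 1, 1))
  expect_error(boltzmann_invert(d, 310, bulk_bins = 1:2), "anchor")
  expect_error(boltzmann_invert(d, 310, bulk_bins = 99), "out of range")
})

test_that("barrier height is the regional maximum relative to bulk", {
  flat <- boltzmann_invert(dens_from_avg(rep(1, 10)), 310, bulk_bins = 1:2)
  expect_equal(barrier_height(flat, c(3, 8))$barrier_kJmol, 0)
  kT <- thermal_energy(310)
  n <- rep(1, 10); n[5] <- exp(-12.3 / kT)
  fep <- boltzmann_invert(dens_from_avg(n), 310, bulk_bins = c(1, 2, 9, 10))
  b <- barrier_height(fep, c(4, 6))
  expect_equal(b$barrier_kJmol, 12.3, tolerance = 1e-9)
  expect_false(b$censored)
  expect_error(barrier_height(fep, c(100, 110)), "no bins")
})

test_that("wetted flat pores classify open; de-wetted pores closed", {
  prof <- ideal_cyl_profile(r = 5, z_min = -10, z_max = 10, step = 1)
  truth <- flat_truth()
  tr <- sample_water_trajectory(truth, area = pi * 25, z_range = c(-10, 10),
                                n_frames = 200, seed = 17)
  occ <- count_occupancy(tr, prof, bin_width = 1)
  dens <- density_map(occ, prof)
  fep <- boltzmann_invert(dens, 310, bulk_bins = c(1:3, 18:20))
  call <- classify_state(occ, fep, c(-4, 4))
  expect_equal(call$verdict, "open")
  expect_equal(call$dewetted_fraction, 0)

  # artificial full de-wetting of the region
  occ2 <- occ
  mid <- occ2$z_centers >= -4 & occ2$z_centers <= 4
  occ2$counts[, mid] <- 0L
  dens2 <- density_map(occ2, prof)
  fep2 <- boltzmann_invert(dens2, 310, bulk_bins = c(1:3, 18:20))
  call2 <- classify_state(occ2, fep2, c(-4, 4))
  expect_equal(call2$dewetted_fraction, 1)
  expect_equal(call2$verdict, "closed")
  expect_true(call2$barrier_censored)
})

test_that("a 12 kJ/mol barrier at 310 K exceeds the 2 kT threshold", {
  kT <- thermal_energy(310)
  n <- rep(1, 12); n[6] <- exp(-12 / kT)
  fep <- boltzmann_invert(dens_from_avg(n), 310, bulk_bins = c(1:2, 11:12))
  occ <- structure(list(z_edges = 0:12, z_centers = (1:12) - 0.5,
                        frame_times = 0:9,
                        counts = matrix(1L, nrow = 10, ncol = 12),
                        bin_width = 1, region_mode = "cylinder",
                        cylinder_radius = 5),
                   class = "occupancy_map")
  call <- classify_state(occ, fep, c(4, 8))
  expect_equal(call$verdict, "closed")
  expect_equal(call$barrier_threshold, 2 * kT)
  expect_gt(call$barrier_kJmol, 2 * kT)
})

test_that("disagreeing signals near threshold are indeterminate", {
  kT <- thermal_energy(310)
  # barrier just below 2 kT (within 10%), de-wetting well above threshold
  n <- rep(1, 12); n[6] <- exp(-1.95 * kT / kT)
  fep <- boltzmann_invert(dens_from_avg(n), 310, bulk_bins = c(1:2, 11:12))
  counts <- matrix(1L, nrow = 10, ncol = 12)
  counts[1:9, 6] <- 0L   # region bin empty in 90% of frames
  counts[, 5] <- 0L; counts[, 7] <- 0L
  counts[10, c(5, 7)] <- 0L; counts[10, 6] <- 1L
  occ <- structure(list(z_edges = 0:12, z_centers = (1:12) - 0.5,
                        frame_times = 0:9, counts = counts,
                        bin_width = 1, region_mode = "cylinder",
                        cylinder_radius = 5),
                   class = "occupancy_map")
  call <- classify_state(occ, fep, c(4.5, 6.5))
  expect_equal(call$verdict, "indeterminate")
})
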