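#' Specification of a pseudo-atom pore wall
#'
#' Geometry for [make_pore_structure()]: a cylinder of constant wall radius,
#' or an hourglass whose wall radius narrows quadratically from the mouths
#' to a waist. `wall_radius` is the axis-to-atom-centre distance, so the
#' open probe radius is `wall_radius - atom_radius` (up to the lattice
#' discretization). The lattice spacing must not exceed the atom radius or
#' a probe could leak between wall atoms.
#'
#' @param shape `"cylinder"` or `"hourglass"`.
#' @param length axial extent in Angstrom (centred on z = 0).
#' @param wall_radius cylinder wall radius, Angstrom.
#' @param mouth_radius,waist_radius,waist_z hourglass geometry, Angstrom.
#' @param atom_radius hard-sphere radius of the wall atoms, Angstrom.
#' @param atom_spacing ring and intra-ring lattice spacing, Angstrom.
#' @return an object of class `pore_spec`.
#' @export
pore_spec <- function(shape = c("cylinder", "hourglass"), length = 20,
                      wall_radius = 6, mouth_radius = 8, waist_radius = 3,
                      waist_z = 0, atom_radius = 1.0, atom_spacing = 1.0) {
  shape <- match.arg(shape)
  if (atom_spacing > atom_radius) {
    stop("atom_spacing must not exceed atom_radius (wall would leak)",
         call. = FALSE)
  }
  if (length <= 0 || atom_radius <= 0) stop("invalid pore_spec", call. = FALSE)
  if (shape == "hourglass" && waist_radius >= mouth_radius) {
    stop("waist_radius must be smaller than mouth_radius", call. = FALSE)
  }
  structure(list(shape = shape, length = length, wall_radius = wall_radius,
                 mouth_radius = mouth_radius, waist_radius = waist_radius,
                 waist_z = waist_z, atom_radius = atom_radius,
                 atom_spacing = atom_spacing),
            class = "pore_spec")
}

#' Build a pseudo-atom pore structure of known geometry
#'
#' Places wall atoms on rings around the z-axis at the wall radius of the
#' chosen shape, with ring spacing equal to `atom_spacing`, alternate rings
#' staggered by half an angular step. Radii are assigned directly from the
#' spec, so the structure is ready for [find_pore_profile()]; it is also
#' writable as PDB via [write_structure()].
#'
#' @param spec a [pore_spec()].
#' @return a `pore_structure` with radii assigned.
#' @export
make_pore_structure <- function(spec) {
  stopifnot(inherits(spec, "pore_spec"))
  half <- spec$length / 2
  z_rings <- seq(-half, half, by = spec$atom_spacing)
  wall_r <- function(z) {
    if (spec$shape == "cylinder") return(rep(spec$wall_radius, length(z)))
    dz <- (z - spec$waist_z) / max(abs(c(-half, half) - spec$waist_z))
    spec$waist_radius + (spec$mouth_radius - spec$waist_radius) * dz^2
  }
  rows <- vector("list", length(z_rings))
  for (i in seq_along(z_rings)) {
    R <- wall_r(z_rings[i])
    n_ring <- max(3L, ceiling(2 * pi * R / spec$atom_spacing))
    theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring +
      (i %% 2) * pi / n_ring  # stagger alternate rings
    rows[[i]] <- data.frame(x = R * cos(theta), y = R * sin(theta),
                            z = z_rings[i])
  }
  xyz <- do.call(rbind, rows)
  atoms <- data.frame(
    element = "C", name = "C",
    residue_name = "POR", residue_index = seq_len(nrow(xyz)),
    chain_id = "A",
    x = xyz$x, y = xyz$y, z = xyz$z,
    radius = spec$atom_radius,
    stringsAsFactors = FALSE
  )
  pore_structure(atoms, label = paste0("synthetic-", spec$shape))
}

#' Ground-truth axial free-energy profile
#'
#' A known profile `E*(z)` (kJ/mol, zero in the bulk) with a bulk density
#' and temperature, used by the samplers below. `E` may be a function of z
#' or a two-column table (`z`, `E`) interpolated linearly.
#'
#' @param E function(z) or data.frame/matrix with columns z, E.
#' @param n_bulk bulk number density, molecules per Angstrom^3.
#' @param temperature_K absolute temperature.
#' @return an object of class `ground_truth_profile`.
#' @export
ground_truth_profile <- function(E, n_bulk = 0.0334, temperature_K = 310) {
  if (!is.function(E)) {
    tab <- as.data.frame(E)
    names(tab)[1:2] <- c("z", "E")
    E <- function(z) approx(tab$z, tab$E, xout = z, rule = 2)$y
  }
  stopifnot(n_bulk > 0, temperature_K > 0)
  structure(list(E = E, n_bulk = n_bulk, temperature_K = temperature_K),
            class = "ground_truth_profile")
}

#' Gaussian barrier helper
#'
#' `E*(z) = height * exp(-(z - center)^2 / (2 sigma^2))`: a single smooth
#' barrier that decays to zero (bulk) at both ends.
#'
#' @param height barrier height in kJ/mol.
#' @param center barrier position in Angstrom.
#' @param sigma Gaussian width in Angstrom.
#' @return function(z).
#' @export
gaussian_barrier <- function(height = 12, center = 0, sigma = 2) {
  function(z) height * exp(-(z - center)^2 / (2 * sigma^2))
}

#' Sample a water trajectory from a prescribed free-energy profile
#'
#' Draws statistically independent frames of water positions as an
#' inhomogeneous Poisson process with axial intensity
#' `lambda(z) = n_bulk * exp(-E*(z)/kT) * area(z)`, uniform over the
#' circular cross-section at each z. This is ideal-gas sampling (no
#' excluded volume, no frame-to-frame correlation): exactly the statistical
#' structure the Boltzmann-inversion analysis assumes.
#'
#' @param truth a [ground_truth_profile()].
#' @param area area in Angstrom^2: a single number or a function of z.
#' @param z_range axial extent sampled, Angstrom.
#' @param n_frames number of frames.
#' @param seed RNG seed; output is fully determined by it.
#' @param dt_ns frame time spacing in ns (default 0.1).
#' @param dz axial discretization of the intensity (default 0.05 Angstrom).
#' @return a `water_trajectory`.
#' @export
sample_water_trajectory <- function(truth, area, z_range, n_frames,
                                    seed = 1L, dt_ns = 0.1, dz = 0.05) {
  stopifnot(inherits(truth, "ground_truth_profile"), n_frames >= 1)
  area_fun <- if (is.function(area)) area else function(z) rep(area, length(z))
  kT <- thermal_energy(truth$temperature_K)
  zc <- seq(z_range[1] + dz / 2, z_range[2] - dz / 2, by = dz)
  lambda <- truth$n_bulk * exp(-truth$E(zc) / kT) * area_fun(zc) * dz
  Lambda <- sum(lambda)
  prob <- lambda / Lambda
  set.seed(seed)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    n <- rpois(1, Lambda)
    if (n == 0L) {
      frames[[f]] <- matrix(numeric(0), ncol = 3)
      next
    }
    cell <- sample.int(length(zc), n, replace = TRUE, prob = prob)
    z <- zc[cell] + runif(n, -dz / 2, dz / 2)
    R_eff <- sqrt(area_fun(z) / pi)
    r <- R_eff * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    frames[[f]] <- cbind(x = r * cos(th), y = r * sin(th), z = z)
  }
  water_trajectory(frames, frame_times = (seq_len(n_frames) - 1) * dt_ns)
}

#' Sample umbrella windows from a known 1-D potential
#'
#' For each restraint centre, draws samples from the exact biased density
#' `p(z) proportional to exp(-(E*(z) + k (z - c)^2 / 2)/kT)` by inverse-CDF
#' lookup on a fine grid (0.01 Angstrom), which keeps discretization bias
#' far below sampling noise.
#'
#' @param true_pmf a [ground_truth_profile()] for the tagged particle.
#' @param centers restraint centres in Angstrom, strictly increasing.
#' @param force_constant harmonic force constant in kJ mol^-1 nm^-2
#'   (default 1000, i.e. 10 kJ mol^-1 A^-2).
#' @param n_samples samples per window.
#' @param seed RNG seed.
#' @param dt_ns sample time spacing in ns (default 0.001).
#' @param grid_dz inverse-CDF grid, Angstrom.
#' @return list of `umbrella_window`.
#' @export
sample_umbrella_windows <- function(true_pmf, centers, force_constant = 1000,
                                    n_samples = 5000L, seed = 1L,
                                    dt_ns = 0.001, grid_dz = 0.01) {
  stopifnot(inherits(true_pmf, "ground_truth_profile"),
            all(diff(centers) > 0), n_samples >= 1)
  kT <- thermal_energy(true_pmf$temperature_K)
  k_A2 <- force_constant * 0.01
  sigma0 <- sqrt(kT / k_A2)
  pad <- max(6 * sigma0, 2)
  zg <- seq(min(centers) - pad, max(centers) + pad, by = grid_dz)
  E_star <- true_pmf$E(zg)
  set.seed(seed)
  edges <- c(zg - grid_dz / 2, zg[length(zg)] + grid_dz / 2)
  lapply(centers, function(ci) {
    u_bias <- E_star + 0.5 * k_A2 * (zg - ci)^2
    logp <- -(u_bias - min(u_bias)) / kT
    p <- exp(logp)
    # CDF at cell *edges* (0 at the lower edge), so the interpolated
    # inverse is free of half-cell shift bias
    cdf <- c(0, cumsum(p))
    cdf <- cdf / cdf[length(cdf)]
    u <- runif(n_samples)
    keep <- c(TRUE, diff(cdf) > 0)
    z <- approx(cdf[keep], edges[keep], xout = u, rule = 2)$y
    umbrella_window(ci, force_constant, z,
                    sample_times = seq_len(n_samples) * dt_ns)
  })
}
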