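# Shared fixtures, all generated in code.

cyl_spec <- function(length = 20, wall_radius = 6, atom_radius = 1,
                     atom_spacing = 1) {
  pore_spec("cylinder", length = length, wall_radius = wall_radius,
            atom_radius = atom_radius, atom_spacing = atom_spacing)
}

cyl_structure <- function(...) make_pore_structure(cyl_spec(...))

flat_truth <- function(n_bulk = 0.0334, temperature_K = 310) {
  ground_truth_profile(function(z) rep(0, length(z)), n_bulk = n_bulk,
                       temperature_K = temperature_K)
}

barrier_truth <- function(height = 12, sigma = 2, n_bulk = 0.0334,
                          temperature_K = 310) {
  ground_truth_profile(gaussian_barrier(height, 0, sigma), n_bulk = n_bulk,
                       temperature_K = temperature_K)
}

# Hand-built profile of an ideal cylinder: radius r everywhere, centre on
# the axis. Lets hydration tests run without the (slower) geometry search.
ideal_cyl_profile <- function(r = 5, z_min = -20, z_max = 20, step = 1) {
  zg <- seq(z_min, z_max, by = step)
  structure(list(z_grid = zg, radius = rep(r, length(zg)),
                 center_path = cbind(cx = rep(0, length(zg)),
                                     cy = rep(0, length(zg))),
                 blocked = rep(FALSE, length(zg)),
                 axis = c(0, 0, 1), origin = c(0, 0, z_min),
                 method = "ideal", seed = NA_integer_),
            class = "pore_profile")
}

# Trajectory with explicitly placed waters: `coords` is a list of n x 3
# matrices (possibly with 0 rows).
traj_from_coords <- function(coords) {
  coords <- lapply(coords, function(m) {
    m <- matrix(m, ncol = 3)
    colnames(m) <- c("x", "y", "z")
    m
  })
  water_trajectory(coords)
}

# Brute-force probe radius independent of the compiled kernel.
probe_oracle <- function(point, structure) {
  at <- structure$atoms
  min(sqrt((at$x - point[1])^2 + (at$y - point[2])^2 +
           (at$z - point[3])^2) - at$radius)
}
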