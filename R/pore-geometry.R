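#' Probe-sphere radius at a point
#'
#' The largest sphere centred at `point` that does not overlap any atom's
#' hard sphere: `min over atoms of (|point - atom| - atom radius)`. May be
#' negative when the point lies inside an atom.
#'
#' @param point numeric 3-vector (Angstrom).
#' @param structure a `pore_structure` with radii assigned.
#' @return probe radius in Angstrom.
#' @export
probe_radius_at <- function(point, structure) {
  .check_geometry_input(structure)
  stopifnot(length(point) == 3L, all(is.finite(point)))
  at <- structure$atoms
  .probe_radius_points(matrix(as.numeric(point), ncol = 3),
                       as.matrix(at[, c("x", "y", "z")]), at$radius)[1]
}

.check_geometry_input <- function(structure) {
  if (!inherits(structure, "pore_structure")) {
    stop("structure must be a pore_structure", call. = FALSE)
  }
  if (nrow(structure$atoms) == 0L) stop("empty structure", call. = FALSE)
  if (anyNA(structure$atoms$radius)) {
    stop("structure has unassigned radii; call assign_radii() first",
         call. = FALSE)
  }
}

#' Simulated-annealing schedule for the slice search
#'
#' @param initial_temperature starting displacement scale in Angstrom.
#' @param cooling_factor geometric cooling per temperature stage, in (0, 1).
#' @param steps_per_temperature Monte-Carlo moves per stage.
#' @param n_temperatures number of stages.
#' @param seed RNG seed making the whole profile deterministic.
#' @return an object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(initial_temperature = 1.0, cooling_factor = 0.9,
                            steps_per_temperature = 50L, n_temperatures = 30L,
                            seed = 1L) {
  stopifnot(initial_temperature > 0, cooling_factor > 0, cooling_factor < 1,
            steps_per_temperature >= 1, n_temperatures >= 1)
  structure(list(initial_temperature = initial_temperature,
                 cooling_factor = cooling_factor,
                 steps_per_temperature = as.integer(steps_per_temperature),
                 n_temperatures = as.integer(n_temperatures),
                 seed = as.integer(seed)),
            class = "anneal_schedule")
}

#' Pore radius profile by annealed probe-sphere search
#'
#' HOLE-style profile: at every z along the pore axis the probe centre is
#' moved in the (x, y) plane by simulated-annealing Monte Carlo to maximise
#' [probe_radius_at()]. Each slice is seeded from the previous slice's
#' optimum and the centre is constrained to move at most `max_center_jump`
#' between adjacent slices, which keeps the centre path continuous through
#' locally symmetric or degenerate slices. The structure must already be
#' oriented with the pore along the z-axis (see [align_principal_axis()]).
#'
#' @param structure a `pore_structure` with radii assigned.
#' @param z_min,z_max axial range in Angstrom (`z_max > z_min`).
#' @param step grid spacing in Angstrom.
#' @param schedule an [anneal_schedule()].
#' @param start_point optional 3-vector seeding the first slice; defaults to
#'   the axis origin `(0, 0)` at `z_min`.
#' @param max_center_jump continuity bound on the centre path, Angstrom.
#' @return a `pore_profile`: `z_grid`, `radius` (>= 0; slices where no
#'   positive radius was found are 0 with `blocked` flag set), `center_path`
#'   (per-z x, y), `axis`, `origin`.
#' @export
find_pore_profile <- function(structure, z_min, z_max, step = 0.5,
                              schedule = anneal_schedule(),
                              start_point = NULL, max_center_jump = 2.0) {
  .check_geometry_input(structure)
  stopifnot(z_max > z_min, step > 0)
  at <- structure$atoms
  coords <- as.matrix(at[, c("x", "y", "z")])
  radii <- at$radius
  z_grid <- seq(z_min, z_max, by = step)
  set.seed(schedule$seed)
  center <- if (is.null(start_point)) c(0, 0) else as.numeric(start_point[1:2])
  n <- length(z_grid)
  radius <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  blocked <- logical(n)
  for (i in seq_len(n)) {
    res <- .anneal_slice(z_grid[i], center, coords, radii, schedule,
                         max_center_jump)
    radius[i] <- max(res$value, 0)
    blocked[i] <- res$value <= 0
    cx[i] <- res$center[1]; cy[i] <- res$center[2]
    center <- res$center
  }
  structure(list(z_grid = z_grid, radius = radius,
                 center_path = cbind(cx = cx, cy = cy),
                 blocked = blocked,
                 axis = c(0, 0, 1), origin = c(0, 0, z_min),
                 method = "anneal", seed = schedule$seed),
            class = "pore_profile")
}

# One slice: maximise probe radius over (x, y) at fixed z, starting from
# `seed_center`, staying within `bound` of it. Uphill moves always accepted;
# downhill with Boltzmann-like probability at the current displacement scale.
.anneal_slice <- function(z, seed_center, coords, radii, schedule, bound) {
  f <- function(xy) {
    .probe_radius_points(matrix(c(xy[1], xy[2], z), ncol = 3), coords, radii)[1]
  }
  cur <- seed_center
  fcur <- f(cur)
  best <- cur; fbest <- fcur
  temp <- schedule$initial_temperature
  for (t in seq_len(schedule$n_temperatures)) {
    for (s in seq_len(schedule$steps_per_temperature)) {
      prop <- cur + runif(2, -temp, temp)
      if (sqrt(sum((prop - seed_center)^2)) > bound) next
      fprop <- f(prop)
      if (fprop > fcur || runif(1) < exp((fprop - fcur) / temp)) {
        cur <- prop; fcur <- fprop
        if (fcur > fbest) { best <- cur; fbest <- fcur }
      }
    }
    temp <- temp * schedule$cooling_factor
  }
  list(center = best, value = fbest)
}

#' @export
print.pore_profile <- function(x, ...) {
  cat("<pore_profile> ", length(x$z_grid), " slices, z ",
      min(x$z_grid), "..", max(x$z_grid), " A, min radius ",
      round(min(x$radius), 2), " A at z = ",
      x$z_grid[which.min(x$radius)], " A\n", sep = "")
  invisible(x)
}

#' Pore radius profile by exhaustive grid search
#'
#' Deterministic reference search: every slice plane is scanned on a square
#' grid (default 0.05 Angstrom) within `bound` of the axis origin, and the
#' exact maximum of the probe radius over grid points is taken. Slow but
#' free of stochastic error; used to validate the annealed search.
#'
#' @inheritParams find_pore_profile
#' @param grid_step plane grid spacing in Angstrom.
#' @param bound half-width of the scanned square, Angstrom.
#' @return a `pore_profile`.
#' @export
find_pore_profile_grid <- function(structure, z_min, z_max, step = 0.5,
                                   grid_step = 0.05, bound = 8) {
  .check_geometry_input(structure)
  stopifnot(z_max > z_min, step > 0, grid_step > 0, bound > 0)
  at <- structure$atoms
  coords <- as.matrix(at[, c("x", "y", "z")])
  radii <- at$radius
  z_grid <- seq(z_min, z_max, by = step)
  g <- seq(-bound, bound, by = grid_step)
  plane <- as.matrix(expand.grid(x = g, y = g))
  n <- length(z_grid)
  radius <- numeric(n); cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    pts <- cbind(plane, z_grid[i])
    vals <- .probe_radius_points(pts, coords, radii)
    k <- which.max(vals)
    radius[i] <- max(vals[k], 0)
    cx[i] <- plane[k, 1]; cy[i] <- plane[k, 2]
  }
  structure(list(z_grid = z_grid, radius = radius,
                 center_path = cbind(cx = cx, cy = cy),
                 blocked = radius <= 0,
                 axis = c(0, 0, 1), origin = c(0, 0, z_min),
                 method = "grid", seed = NA_integer_),
            class = "pore_profile")
}

#' Circular cross-sectional area at a position
#'
#' Interpolates the radius profile linearly and returns `pi * r(z)^2`,
#' the local pore cross-section approximated as circular.
#'
#' @param profile a `pore_profile`.
#' @param z axial position(s) in Angstrom, within the profile range.
#' @return area(s) in Angstrom^2.
#' @export
cross_section_area <- function(profile, z) {
  stopifnot(inherits(profile, "pore_profile"))
  rng <- range(profile$z_grid)
  if (any(z < rng[1] | z > rng[2])) {
    stop("z outside profile range [", rng[1], ", ", rng[2], "]", call. = FALSE)
  }
  r <- approx(profile$z_grid, profile$radius, xout = z)$y
  pi * r^2
}

#' Align the principal axis of a structure to z
#'
#' Optional pre-step for structures not already in a membrane frame:
#' centres the coordinates and rotates so that the principal axis of the
#' atom cloud (largest-variance direction) maps onto +z.
#'
#' @param structure a `pore_structure`.
#' @return the rotated structure.
#' @export
align_principal_axis <- function(structure) {
  stopifnot(inherits(structure, "pore_structure"))
  xyz <- as.matrix(structure$atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  sv <- svd(xc, nu = 0)
  rot <- sv$v[, c(2, 3, 1)]  # principal axis -> third column (z)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  out <- xc %*% rot
  structure$atoms$x <- out[, 1]
  structure$atoms$y <- out[, 2]
  structure$atoms$z <- out[, 3]
  structure
}

#' Write a pore profile as TSV
#'
#' Columns `z_A`, `radius_A`, `cx_A`, `cy_A`, `blocked`.
#'
#' @param profile a `pore_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pore_profile <- function(profile, path) {
  stopifnot(inherits(profile, "pore_profile"))
  write_profile_tsv(
    data.frame(z_A = profile$z_grid, radius_A = profile$radius,
               cx_A = profile$center_path[, "cx"],
               cy_A = profile$center_path[, "cy"],
               blocked = as.integer(profile$blocked)),
    path
  )
}

#' Read a pore profile written by [write_pore_profile()]
#'
#' @param path TSV path.
#' @return a `pore_profile`.
#' @export
read_pore_profile <- function(path) {
  tab <- read_profile_tsv(path)
  structure(list(z_grid = tab$z_A, radius = tab$radius_A,
                 center_path = cbind(cx = tab$cx_A, cy = tab$cy_A),
                 blocked = as.logical(tab$blocked),
                 axis = c(0, 0, 1), origin = c(0, 0, tab$z_A[1]),
                 method = "file", seed = NA_integer_),
            class = "pore_profile")
}
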