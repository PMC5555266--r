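# Default bulk number density of water, molecules per A^3 (~310 K).
.default_n_bulk <- 0.0334

#' Count pore waters per axial bin per frame
#'
#' Bins water oxygens along z within the pore region. A water at axial
#' coordinate z and radial distance d from the pore centre path is counted
#' in bin(z) iff `d <= r(z)` (`hole-surface` mode, radius and centre
#' interpolated from the profile) or `d <= cylinder_radius` (`cylinder`
#' mode, centre fixed at the axis origin). Bins are uniform, contiguous,
#' half-open `[lo, hi)`; each water falls in at most one bin per frame.
#'
#' @param trajectory a `water_trajectory` in the same frame as `profile`.
#' @param profile a `pore_profile` (required in `hole-surface` mode; in
#'   `cylinder` mode it may be omitted if `z_range` is given).
#' @param bin_width axial bin width in Angstrom (default 1).
#' @param region_mode `"hole-surface"` or `"cylinder"`.
#' @param cylinder_radius radial cutoff in Angstrom (cylinder mode).
#' @param z_range optional axial range; defaults to the profile range.
#' @return an `occupancy_map`: `z_edges`, `z_centers`, `frame_times`,
#'   `counts` (frames x bins integer matrix), `region_mode`,
#'   `cylinder_radius`.
#' @export
count_occupancy <- function(trajectory, profile = NULL, bin_width = 1.0,
                            region_mode = c("hole-surface", "cylinder"),
                            cylinder_radius = NULL, z_range = NULL) {
  stopifnot(inherits(trajectory, "water_trajectory"), bin_width > 0)
  region_mode <- match.arg(region_mode)
  if (region_mode == "hole-surface" && is.null(profile)) {
    stop("hole-surface mode needs a pore_profile", call. = FALSE)
  }
  if (region_mode == "cylinder" && is.null(cylinder_radius)) {
    stop("cylinder mode needs cylinder_radius", call. = FALSE)
  }
  if (is.null(z_range)) {
    if (is.null(profile)) stop("need z_range or a profile", call. = FALSE)
    z_range <- range(profile$z_grid)
  }
  n_bins <- floor((z_range[2] - z_range[1]) / bin_width + 1e-9)
  if (n_bins < 1L) stop("no bins fit in the given z range", call. = FALSE)
  edges <- z_range[1] + bin_width * (0:n_bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nf <- length(trajectory$frames)
  counts <- matrix(0L, nrow = nf, ncol = n_bins)
  for (fi in seq_len(nf)) {
    w <- trajectory$frames[[fi]]
    if (nrow(w) == 0L) next
    inside_z <- w[, 3] >= edges[1] & w[, 3] < edges[length(edges)]
    w <- w[inside_z, , drop = FALSE]
    if (nrow(w) == 0L) next
    if (region_mode == "cylinder") {
      d <- sqrt(w[, 1]^2 + w[, 2]^2)
      ok <- d <= cylinder_radius
    } else {
      cx <- approx(profile$z_grid, profile$center_path[, "cx"], xout = w[, 3],
                   rule = 2)$y
      cy <- approx(profile$z_grid, profile$center_path[, "cy"], xout = w[, 3],
                   rule = 2)$y
      r <- approx(profile$z_grid, profile$radius, xout = w[, 3], rule = 2)$y
      ok <- sqrt((w[, 1] - cx)^2 + (w[, 2] - cy)^2) <= r
    }
    if (!any(ok)) next
    idx <- findInterval(w[ok, 3], edges, rightmost.closed = FALSE)
    counts[fi, ] <- tabulate(idx, nbins = n_bins)
  }
  structure(list(z_edges = edges, z_centers = centers,
                 frame_times = trajectory$frame_times,
                 counts = counts, bin_width = bin_width,
                 region_mode = region_mode,
                 cylinder_radius = cylinder_radius),
            class = "occupancy_map")
}

#' @export
print.occupancy_map <- function(x, ...) {
  cat("<occupancy_map> ", nrow(x$counts), " frames x ", ncol(x$counts),
      " bins (", x$bin_width, " A, ", x$region_mode, "), mean occupancy ",
      round(mean(x$counts), 2), "\n", sep = "")
  invisible(x)
}

#' Bulk-normalized water density map and time-averaged profile
#'
#' Converts per-bin water counts to number densities by dividing by the
#' local slab volume `area(z) * bin_width` (area from the radius profile in
#' hole-surface mode, `pi * cylinder_radius^2` in cylinder mode), then
#' normalizes to the bulk density so that unconfined water sits at 1.
#' Per-frame densities are computed first and then averaged, so the
#' time-resolved map and its average are mutually consistent.
#'
#' @param occupancy an `occupancy_map`.
#' @param profile the matching `pore_profile` (hole-surface mode).
#' @param n_bulk bulk water number density in molecules per Angstrom^3
#'   (default 0.0334, pure water near 310 K).
#' @return a `density_profile`: `z_centers`, `per_frame` (frames x bins),
#'   `average`, `undefined` (bins with zero area, not divided), `n_bulk`,
#'   `frames_used`.
#' @export
density_map <- function(occupancy, profile = NULL,
                        n_bulk = .default_n_bulk) {
  stopifnot(inherits(occupancy, "occupancy_map"), n_bulk > 0)
  if (occupancy$region_mode == "cylinder") {
    area <- rep(pi * occupancy$cylinder_radius^2, length(occupancy$z_centers))
  } else {
    if (is.null(profile)) stop("hole-surface mode needs the profile", call. = FALSE)
    area <- cross_section_area(profile, occupancy$z_centers)
  }
  undefined <- area <= 0
  if (all(undefined)) stop("pore area is zero in every bin", call. = FALSE)
  denom <- area * occupancy$bin_width * n_bulk
  per_frame <- sweep(occupancy$counts, 2, denom, "/")
  per_frame[, undefined] <- NA_real_
  avg <- colMeans(per_frame)
  structure(list(z_centers = occupancy$z_centers,
                 per_frame = per_frame, average = avg,
                 undefined = undefined, area = area,
                 bin_width = occupancy$bin_width,
                 n_bulk = n_bulk, frames_used = nrow(occupancy$counts),
                 frame_times = occupancy$frame_times),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("<density_profile> ", length(x$z_centers), " bins, ",
      x$frames_used, " frames, n_bulk ", x$n_bulk,
      " A^-3, mean n/n_bulk ", round(mean(x$average, na.rm = TRUE), 3),
      "\n", sep = "")
  invisible(x)
}

#' Estimate bulk water density from a trajectory region
#'
#' Mean water count over frames in a user-chosen region far from the pore,
#' divided by the region volume. The region is a z-interval combined with
#' either a radial bound (cylinder of radius `radius` about the axis) or a
#' square cross-section of half-width `xy_halfwidth`. Estimates outside the
#' plausible aqueous range (0.02, 0.05) molecules/A^3 trigger a warning.
#'
#' @param trajectory a `water_trajectory`.
#' @param z_range length-2 numeric, Angstrom.
#' @param radius cylinder radius in Angstrom (exclusive with `xy_halfwidth`).
#' @param xy_halfwidth half-width of a square xy cross-section, Angstrom.
#' @return bulk number density in molecules per Angstrom^3.
#' @export
estimate_bulk_density <- function(trajectory, z_range, radius = NULL,
                                  xy_halfwidth = NULL) {
  stopifnot(inherits(trajectory, "water_trajectory"))
  if (length(z_range) != 2L || diff(z_range) <= 0) {
    stop("z_range must be an increasing interval", call. = FALSE)
  }
  if (is.null(radius) == is.null(xy_halfwidth)) {
    stop("give exactly one of radius or xy_halfwidth", call. = FALSE)
  }
  len <- diff(z_range)
  if (!is.null(radius)) {
    if (radius <= 0) stop("empty bulk region", call. = FALSE)
    volume <- pi * radius^2 * len
  } else {
    if (xy_halfwidth <= 0) stop("empty bulk region", call. = FALSE)
    volume <- (2 * xy_halfwidth)^2 * len
  }
  counts <- vapply(trajectory$frames, function(w) {
    if (nrow(w) == 0L) return(0)
    inz <- w[, 3] >= z_range[1] & w[, 3] < z_range[2]
    w <- w[inz, , drop = FALSE]
    if (!is.null(radius)) {
      sum(sqrt(w[, 1]^2 + w[, 2]^2) <= radius)
    } else {
      sum(abs(w[, 1]) <= xy_halfwidth & abs(w[, 2]) <= xy_halfwidth)
    }
  }, 1.0)
  est <- mean(counts) / volume
  if (est <= 0.02 || est >= 0.05) {
    warning("bulk density estimate ", signif(est, 3),
            " A^-3 outside the aqueous range (0.02, 0.05)", call. = FALSE)
  }
  est
}

#' Write a density map and averaged profile as TSV
#'
#' The map file has one row per (frame, bin): `frame_time_ns`, `z_center_A`,
#' `n_normalized`. The averaged profile has `z_center_A`,
#' `n_normalized_mean` with `frames_used` and `n_bulk` recorded in header
#' comments.
#'
#' @param density a `density_profile`.
#' @param map_path,profile_path output paths (either may be `NULL`).
#' @return invisibly, the paths written.
#' @export
write_density <- function(density, map_path = NULL, profile_path = NULL) {
  stopifnot(inherits(density, "density_profile"))
  if (!is.null(map_path)) {
    nf <- nrow(density$per_frame)
    nb <- ncol(density$per_frame)
    write_profile_tsv(
      data.frame(frame_time_ns = rep(density$frame_times, each = nb),
                 z_center_A = rep(density$z_centers, times = nf),
                 n_normalized = as.vector(t(density$per_frame))),
      map_path,
      extra_header = c(paste("n_bulk_A3", density$n_bulk),
                       paste("frames_used", density$frames_used))
    )
  }
  if (!is.null(profile_path)) {
    write_profile_tsv(
      data.frame(z_center_A = density$z_centers,
                 n_normalized_mean = density$average,
                 undefined = as.integer(density$undefined)),
      profile_path,
      extra_header = c(paste("n_bulk_A3", density$n_bulk),
                       paste("frames_used", density$frames_used),
                       paste("bin_width_A", density$bin_width))
    )
  }
  invisible(c(map_path, profile_path))
}

#' Read an averaged density profile written by [write_density()]
#'
#' Rebuilds a minimal `density_profile` (average only; the per-frame matrix
#' is a single pooled row) suitable for [boltzmann_invert()].
#'
#' @param path profile TSV path.
#' @return a `density_profile`.
#' @export
read_density_profile <- function(path) {
  tab <- read_profile_tsv(path)
  meta <- attr(tab, "meta")
  getm <- function(key, default) {
    hit <- grep(paste0("^", key, " "), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(paste0("^", key, " "), "", hit[1])) else default
  }
  avg <- tab$n_normalized_mean
  structure(list(z_centers = tab$z_center_A,
                 per_frame = matrix(avg, nrow = 1),
                 average = avg,
                 undefined = if (!is.null(tab$undefined)) as.logical(tab$undefined)
                             else rep(FALSE, length(avg)),
                 area = NULL,
                 bin_width = getm("bin_width_A", NA_real_),
                 n_bulk = getm("n_bulk_A3", .default_n_bulk),
                 frames_used = as.integer(getm("frames_used", 1)),
                 frame_times = 0),
            class = "density_profile")
}
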