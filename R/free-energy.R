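#' Boltzmann inversion of a water density profile
#'
#' At equilibrium the axial number density of water and the free energy of a
#' water molecule are related by `n(z) = C exp(-E(z)/kT)`. Inverting gives
#' `E(z) = -kT ln n(z) + kT ln C`, where the additive constant is fixed by
#' setting the free energy of bulk water (outside the pore) to zero: `C` is
#' taken as the mean of the time-averaged normalized density over the
#' designated bulk bins.
#'
#' Bins whose time-averaged density is exactly zero (fully de-wetted over
#' the sampled frames) have no finite inversion; their free energy is a
#' lower bound. With `zero_handling = "cap"` they receive
#' `E_cap = -kT ln(eps) + kT ln(n_bulk_bins)` with the pseudo-density
#' `eps = 1/(frames_used + 1)` in normalized units, and the `censored` flag
#' set; with `"censor-only"` they are `NA` with the flag set.
#'
#' @param density a `density_profile` (time-averaged values are used).
#' @param temperature_K absolute temperature (default 310 K).
#' @param bulk_bins integer indices of bins treated as bulk; their mean
#'   density anchors the zero of energy.
#' @param zero_handling `"cap"` or `"censor-only"`.
#' @return a `free_energy_profile`: `z_centers`, `E` (kJ/mol, bulk = 0),
#'   `censored`, `temperature_K`, `kT`, `E_cap`, `offset_kJmol`
#'   (the additive constant `kT ln C`), `bulk_bins`.
#' @export
boltzmann_invert <- function(density, temperature_K = 310,
                             bulk_bins, zero_handling = c("cap", "censor-only")) {
  stopifnot(inherits(density, "density_profile"))
  zero_handling <- match.arg(zero_handling)
  kT <- thermal_energy(temperature_K)
  nbar <- density$average
  nb <- length(nbar)
  if (missing(bulk_bins) || length(bulk_bins) == 0L) {
    stop("bulk_bins must name at least one bin", call. = FALSE)
  }
  if (any(bulk_bins < 1L | bulk_bins > nb)) {
    stop("bulk_bins out of range 1..", nb, call. = FALSE)
  }
  bulk_mean <- mean(nbar[bulk_bins], na.rm = TRUE)
  if (!is.finite(bulk_mean) || bulk_mean <= 0) {
    stop("zero mean density in bulk bins: cannot anchor the constant C",
         call. = FALSE)
  }
  offset <- kT * log(bulk_mean)
  eps <- 1 / (density$frames_used + 1)
  E_cap <- -kT * log(eps) + offset
  E <- -kT * log(nbar) + offset
  censored <- !is.na(nbar) & nbar == 0
  E[censored] <- if (zero_handling == "cap") E_cap else NA_real_
  E[is.na(nbar)] <- NA_real_
  structure(list(z_centers = density$z_centers, E = E, censored = censored,
                 temperature_K = temperature_K, kT = kT, E_cap = E_cap,
                 offset_kJmol = offset, bulk_bins = as.integer(bulk_bins),
                 frames_used = density$frames_used),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("<free_energy_profile> ", length(x$z_centers), " bins at ",
      x$temperature_K, " K, max E ", round(max(x$E, na.rm = TRUE), 2),
      " kJ/mol", if (any(x$censored)) paste0(" (", sum(x$censored),
      " censored bin(s), E_cap ", round(x$E_cap, 2), ")"), "\n", sep = "")
  invisible(x)
}

#' Barrier height of a free-energy profile over a region
#'
#' Maximum of E over the bins whose centres fall in `region`, relative to
#' the bulk baseline (0 by construction). If the maximum sits on a censored
#' bin the returned height is itself a lower bound and is flagged.
#'
#' @param profile a `free_energy_profile`.
#' @param region length-2 z-interval in Angstrom.
#' @return list with `barrier_kJmol` and `censored`.
#' @export
barrier_height <- function(profile, region) {
  stopifnot(inherits(profile, "free_energy_profile"), length(region) == 2L)
  sel <- profile$z_centers >= region[1] & profile$z_centers <= region[2]
  if (!any(sel)) stop("region overlaps no bins", call. = FALSE)
  E <- profile$E[sel]
  if (all(is.na(E))) stop("region has no finite free energies", call. = FALSE)
  k <- which.max(E)
  list(barrier_kJmol = E[k], censored = profile$censored[sel][k])
}

#' Classify a pore region as open or closed
#'
#' Combines two signals over a z-region: the water free-energy barrier and
#' the de-wetted fraction (fraction of frames with zero water in the
#' region). Verdict `closed` when the barrier reaches `barrier_threshold`
#' (default `2 kT`) or the de-wetted fraction reaches `dewet_threshold`
#' (default 0.5); `open` when both are below; `indeterminate` when the two
#' signals disagree and the deciding quantity sits within 10% of its
#' threshold.
#'
#' @param occupancy an `occupancy_map` over (at least) the region.
#' @param profile a `free_energy_profile` on the same binning.
#' @param region length-2 z-interval in Angstrom.
#' @param barrier_threshold kJ/mol; default `2 * kT` at the profile's
#'   temperature.
#' @param dewet_threshold fraction in [0, 1].
#' @return a `state_call`: `region`, `barrier_kJmol`, `barrier_censored`,
#'   `dewetted_fraction`, `verdict`, and the thresholds used.
#' @export
classify_state <- function(occupancy, profile, region,
                           barrier_threshold = NULL, dewet_threshold = 0.5) {
  stopifnot(inherits(occupancy, "occupancy_map"),
            inherits(profile, "free_energy_profile"))
  if (is.null(barrier_threshold)) barrier_threshold <- 2 * profile$kT
  b <- barrier_height(profile, region)
  sel <- occupancy$z_centers >= region[1] & occupancy$z_centers <= region[2]
  if (!any(sel)) stop("region overlaps no occupancy bins", call. = FALSE)
  region_counts <- rowSums(occupancy$counts[, sel, drop = FALSE])
  dewet <- mean(region_counts == 0)
  closed_by_barrier <- b$barrier_kJmol >= barrier_threshold
  closed_by_dewet <- dewet >= dewet_threshold
  near <- function(x, thr) abs(x - thr) <= 0.1 * thr
  verdict <- if (closed_by_barrier != closed_by_dewet &&
                 (near(b$barrier_kJmol, barrier_threshold) ||
                  near(dewet, dewet_threshold))) {
    "indeterminate"
  } else if (closed_by_barrier || closed_by_dewet) {
    "closed"
  } else {
    "open"
  }
  structure(list(region = region,
                 barrier_kJmol = b$barrier_kJmol,
                 barrier_censored = b$censored,
                 dewetted_fraction = dewet,
                 verdict = verdict,
                 barrier_threshold = barrier_threshold,
                 dewet_threshold = dewet_threshold,
                 temperature_K = profile$temperature_K),
            class = "state_call")
}

#' @export
print.state_call <- function(x, ...) {
  cat("<state_call> region [", x$region[1], ", ", x$region[2], "] A: ",
      toupper(x$verdict), " (barrier ",
      if (x$barrier_censored) ">= " else "",
      round(x$barrier_kJmol, 2), " kJ/mol vs ",
      round(x$barrier_threshold, 2), "; de-wetted fraction ",
      round(x$dewetted_fraction, 3), " vs ", x$dewet_threshold, ")\n",
      sep = "")
  invisible(x)
}

#' Write a free-energy profile as TSV
#'
#' Columns `z_center_A`, `E_kJmol`, `censored`.
#'
#' @param profile a `free_energy_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_free_energy <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  write_profile_tsv(
    data.frame(z_center_A = profile$z_centers,
               E_kJmol = profile$E,
               censored = as.integer(profile$censored)),
    path,
    extra_header = c(paste("temperature_K", profile$temperature_K),
                     paste("E_cap_kJmol", profile$E_cap))
  )
}
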