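#' Solve WHAM for a set of umbrella windows
#'
#' Standard self-consistent weighted-histogram equations for 1-D harmonic
#' umbrella sampling. With per-window histograms `h_i(z)`, sample counts
#' `N_i` and bias `w_i(z) = k_i (z - c_i)^2 / 2`:
#' \deqn{P(z) \propto \frac{\sum_i h_i(z)}{\sum_i N_i \exp((f_i - w_i(z))/kT)},
#'       \quad f_i = -kT \ln \sum_z P(z) e^{-w_i(z)/kT}}
#' iterated until the window free energies `f_i` change by less than `tol`.
#' The PMF is `G(z) = -kT ln P(z)` shifted so its minimum is 0.
#'
#' Adjacent windows must share at least one occupied bin; otherwise the
#' result is flagged unconverged with a warning. In the unbiased limit
#' (one window, force constant ~0) the result reduces exactly to Boltzmann
#' inversion of the raw histogram.
#'
#' @param windows list of `umbrella_window`.
#' @param bin_width PMF bin width in Angstrom (default 0.2; finer than the
#'   1 Angstrom window spacing because each window samples densely).
#' @param temperature_K absolute temperature (default 310 K).
#' @param tol convergence tolerance on `f_i` in kJ/mol.
#' @param max_iter iteration cap.
#' @param z_range optional fixed binning range (used by the bootstrap so
#'   replicates share bins); defaults to the sample range.
#' @param weights optional list of per-sample weights per window (Bayesian
#'   bootstrap); each vector is renormalized to the window's sample count.
#' @return a `pmf`: `z_centers`, `G` (kJ/mol, min 0, `NA` in unoccupied
#'   bins), `stderr` (`NA` until [bootstrap_pmf()]), `f` (window free
#'   energies), `n_iterations`, `converged`.
#' @export
solve_wham <- function(windows, bin_width = 0.2, temperature_K = 310,
                       tol = 1e-6, max_iter = 100000L, z_range = NULL,
                       weights = NULL) {
  if (length(windows) == 0L) stop("no umbrella windows", call. = FALSE)
  stopifnot(all(vapply(windows, inherits, TRUE, "umbrella_window")),
            bin_width > 0)
  kT <- thermal_energy(temperature_K)
  ord <- order(vapply(windows, `[[`, 1.0, "center_z"))
  windows <- windows[ord]
  if (!is.null(weights)) weights <- weights[ord]
  all_z <- unlist(lapply(windows, `[[`, "samples"))
  # Default support: the restrained span. Bins far outside the window
  # centres hold a few tail samples against an exploding reweighting
  # factor, so their G estimates are pure noise; excluding them keeps the
  # min-0 alignment on well-sampled bins. A single window has no span, so
  # fall back to its sample range (the unbiased-histogram limit).
  if (is.null(z_range)) {
    ctrs <- vapply(windows, `[[`, 1.0, "center_z")
    z_range <- if (length(windows) > 1L) range(ctrs) else range(all_z)
  }
  n_bins <- max(1L, ceiling((z_range[2] - z_range[1]) / bin_width - 1e-9))
  edges <- z_range[1] + bin_width * (0:n_bins)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  nw <- length(windows)

  h <- matrix(0, nrow = nw, ncol = n_bins)
  N <- numeric(nw)
  for (i in seq_len(nw)) {
    s <- windows[[i]]$samples
    idx <- findInterval(s, edges, rightmost.closed = TRUE)
    keep <- idx >= 1L & idx <= n_bins
    idx <- idx[keep]
    if (is.null(weights)) {
      h[i, ] <- tabulate(idx, nbins = n_bins)
      N[i] <- sum(h[i, ])
    } else {
      w <- weights[[i]][keep]
      w <- w / sum(w) * length(idx)          # total weight = sample count
      for (b in seq_along(idx)) h[i, idx[b]] <- h[i, idx[b]] + w[b]
      N[i] <- sum(h[i, ])
    }
  }
  if (any(N == 0)) stop("a window has no samples inside the binning range",
                        call. = FALSE)

  overlap_ok <- TRUE
  if (nw > 1L) {
    for (i in seq_len(nw - 1L)) {
      if (!any(h[i, ] > 0 & h[i + 1L, ] > 0)) { overlap_ok <- FALSE; break }
    }
    if (!overlap_ok) {
      warning("adjacent umbrella windows share no occupied bin; ",
              "PMF flagged unconverged", call. = FALSE)
    }
  }

  # bias Boltzmann factors, windows x bins
  k_A2 <- vapply(windows, `[[`, 1.0, "force_constant_A2")
  c_z <- vapply(windows, `[[`, 1.0, "center_z")
  W <- 0.5 * k_A2 * outer(c_z, centers, function(ci, zb) (zb - ci)^2)
  B <- exp(-W / kT)
  h_tot <- colSums(h)
  occupied <- h_tot > 0

  f <- numeric(nw)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- colSums(N * exp(f / kT) * B)
    P <- ifelse(denom > 0, h_tot / denom, 0)
    P <- P / sum(P)
    f_new <- -kT * log(as.numeric(B %*% P))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || iter >= max_iter) break
  }
  converged <- overlap_ok && delta < tol

  G <- rep(NA_real_, n_bins)
  G[occupied] <- -kT * log(P[occupied])
  G <- G - min(G, na.rm = TRUE)
  structure(list(z_centers = centers, G = G,
                 stderr = rep(NA_real_, n_bins),
                 f = f, n_iterations = iter, converged = converged,
                 bin_width = bin_width, z_range = z_range,
                 temperature_K = temperature_K, kT = kT,
                 occupied = occupied),
            class = "pmf")
}

#' @export
print.pmf <- function(x, ...) {
  cat("<pmf> ", sum(x$occupied), " occupied bins (", x$bin_width,
      " A), max G ", round(max(x$G, na.rm = TRUE), 2), " kJ/mol, ",
      x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Bayesian-bootstrap error bands for a WHAM PMF
#'
#' Each replicate draws Dirichlet(1, ..., 1) weights over every window's
#' samples, re-solves WHAM with the weighted histograms, aligns the
#' replicate PMF to minimum 0, and the per-bin standard deviation across
#' replicates is reported as the standard error.
#'
#' @inheritParams solve_wham
#' @param n_boot number of bootstrap replicates (>= 2).
#' @param seed RNG seed; the replicate stream is fully determined by it.
#' @param weight_sampler internal hook: function(n) returning n positive
#'   weights; defaults to unit-rate gamma draws (Dirichlet up to scale).
#' @return the `pmf` from the full data with `stderr` filled in, plus
#'   `n_boot` and `n_failed` fields.
#' @export
bootstrap_pmf <- function(windows, bin_width = 0.2, temperature_K = 310,
                          n_boot = 50L, seed = 1L, tol = 1e-6,
                          max_iter = 100000L, weight_sampler = NULL) {
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  base <- solve_wham(windows, bin_width, temperature_K, tol, max_iter)
  if (is.null(weight_sampler)) weight_sampler <- function(n) rgamma(n, 1)
  set.seed(seed)
  reps <- matrix(NA_real_, nrow = n_boot, ncol = length(base$z_centers))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    wts <- lapply(windows, function(w) weight_sampler(length(w$samples)))
    g <- tryCatch(
      solve_wham(windows, bin_width, temperature_K, tol, max_iter,
                 z_range = base$z_range, weights = wts)$G,
      error = function(e) NULL
    )
    if (is.null(g)) n_failed <- n_failed + 1L else reps[r, ] <- g
  }
  if (n_failed >= 0.2 * n_boot) {
    stop(n_failed, "/", n_boot, " bootstrap replicates failed", call. = FALSE)
  }
  base$stderr <- apply(reps, 2, function(col) {
    ok <- !is.na(col)
    if (sum(ok) >= 2L) sd(col[ok]) else NA_real_
  })
  base$n_boot <- n_boot
  base$n_failed <- n_failed
  base
}

#' PMF convergence over consecutive time fractions
#'
#' Splits every window's time series into `n_fractions` equal consecutive
#' blocks, solves WHAM per block on a shared binning, and summarizes the
#' maximum discrepancy between consecutive block PMFs (after aligning each
#' to minimum 0, over bins occupied in both). A block in which some window
#' has no samples is flagged and skipped in the discrepancy summary.
#'
#' @inheritParams solve_wham
#' @param n_fractions number of consecutive blocks (>= 2).
#' @return list with `pmfs` (one per block, `NULL` where flagged),
#'   `flagged` (logical per block), `max_discrepancy_kJmol`, and
#'   `stationary` (`TRUE` when no flags and the discrepancy is finite).
#' @export
convergence_by_fractions <- function(windows, n_fractions = 2L,
                                     bin_width = 0.2, temperature_K = 310,
                                     tol = 1e-6, max_iter = 100000L) {
  if (n_fractions < 2L) stop("n_fractions must be >= 2", call. = FALSE)
  # blocks must share one binning; cover both the restrained span and all
  # samples so a drifted block still bins (drift detection is the point)
  all_z <- range(unlist(lapply(windows, `[[`, "samples")))
  ctr_rng <- range(vapply(windows, `[[`, 1.0, "center_z"))
  z_range <- range(c(all_z, ctr_rng))
  pmfs <- vector("list", n_fractions)
  flagged <- logical(n_fractions)
  for (b in seq_len(n_fractions)) {
    block <- lapply(windows, function(w) {
      n <- length(w$samples)
      ord <- order(w$sample_times)
      cuts <- floor(n * (0:n_fractions) / n_fractions)
      if (cuts[b + 1L] <= cuts[b]) return(NULL)
      idx <- ord[(cuts[b] + 1L):cuts[b + 1L]]
      umbrella_window(w$center_z, w$force_constant,
                      w$samples[idx], w$sample_times[idx])
    })
    if (any(vapply(block, is.null, TRUE))) {
      flagged[b] <- TRUE
      next
    }
    res <- tryCatch(
      solve_wham(block, bin_width, temperature_K, tol, max_iter,
                 z_range = z_range),
      error = function(e) NULL
    )
    if (is.null(res)) flagged[b] <- TRUE else pmfs[[b]] <- res
  }
  # compare consecutive blocks over the well-sampled restrained span,
  # re-aligning each to min 0 on the shared occupied bins
  disc <- NA_real_
  for (b in seq_len(n_fractions - 1L)) {
    if (flagged[b] || flagged[b + 1L]) next
    g1 <- pmfs[[b]]$G; g2 <- pmfs[[b + 1L]]$G
    zc <- pmfs[[b]]$z_centers
    ok <- !is.na(g1) & !is.na(g2) &
      (length(windows) == 1L | (zc >= ctr_rng[1] & zc <= ctr_rng[2]))
    if (any(ok)) {
      d <- max(abs((g1[ok] - min(g1[ok])) - (g2[ok] - min(g2[ok]))))
      disc <- if (is.na(disc)) d else max(disc, d)
    }
  }
  list(pmfs = pmfs, flagged = flagged,
       max_discrepancy_kJmol = disc,
       stationary = !any(flagged) && is.finite(disc))
}

#' Write a PMF as TSV
#'
#' Columns `z_A`, `G_kJmol`, `stderr_kJmol`.
#'
#' @param pmf a `pmf`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmf <- function(pmf, path) {
  stopifnot(inherits(pmf, "pmf"))
  write_profile_tsv(
    data.frame(z_A = pmf$z_centers, G_kJmol = pmf$G,
               stderr_kJmol = pmf$stderr),
    path,
    extra_header = c(paste("temperature_K", pmf$temperature_K),
                     paste("converged", as.integer(pmf$converged)))
  )
}
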