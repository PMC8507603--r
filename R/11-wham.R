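# Weighted histogram analysis method (WHAM) for 1D harmonic umbrella
# sampling, with block bootstrap errors, well depths and well-depth
# differences between membrane compositions.

#' WHAM settings
#'
#' @param bin_width Histogram bin width (nm), default 0.05 (matching the
#'   standard window spacing).
#' @param tolerance Convergence tolerance on the window free-energy shifts
#'   (kT), default 1e-7.
#' @param max_iterations Iteration cap, default 1e5.
#' @param temperature Kelvin, default 323.
#' @param equilibration_skip Extra fraction of each window's samples to skip
#'   (on top of the window's own flagged equilibration), default 0.
#' @param n_bootstrap Bootstrap replicates for [bootstrap_pmf()], default 50.
#' @param min_counts Bins with fewer pooled samples are reported as
#'   unoccupied (NA), default 5; single-sample tail bins otherwise produce
#'   spurious free-energy dips.
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `wham_settings`.
#' @export
wham_settings <- function(bin_width = 0.05, tolerance = 1e-7,
                          max_iterations = 1e5, temperature = 323,
                          equilibration_skip = 0, n_bootstrap = 50,
                          min_counts = 5, seed = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (tolerance <= 0) stop("tolerance must be positive")
  structure(
    list(bin_width = bin_width, tolerance = tolerance,
         max_iterations = max_iterations, temperature = temperature,
         equilibration_skip = equilibration_skip,
         n_bootstrap = n_bootstrap, min_counts = min_counts, seed = seed),
    class = "wham_settings"
  )
}

# Production samples of a window (equilibration removed).
window_production <- function(w, extra_skip_fraction = 0) {
  s <- w$samples
  skip <- w$n_equil_skipped + floor(extra_skip_fraction *
                                      (length(s) - w$n_equil_skipped))
  if (skip >= length(s)) stop("equilibration skip leaves no samples")
  s[(skip + 1):length(s)]
}

#' Estimate a potential of mean force from umbrella windows (WHAM)
#'
#' Standard self-consistent WHAM iteration in kT units: with histogram
#' counts h_b, window sizes N_i and bias factors c_ib = exp(-w_i(x_b)/kT),
#' iterate p_b = h_b / sum_i N_i exp(f_i) c_ib and
#' exp(-f_i) = sum_b p_b c_ib until the largest change in any f_i falls
#' below `tolerance`. G(x) = -kT log p is anchored to a zero count-weighted
#' mean over the outermost plateau (the occupied bins within
#' `anchor_width` = 0.5 nm of the largest occupied bin). Bins with fewer
#' than `min_counts` pooled samples are reported as NA.
#'
#' @param windows List of `umbrella_window` with pairwise overlapping
#'   histograms along the chain.
#' @param settings A `wham_settings`.
#' @param anchor_width Width of the far-distance anchor plateau (nm).
#' @return Object of class `pmf_profile`: `bin_centers` (= `z`), `g`
#'   (kJ/mol), `g_err` (NULL until [bootstrap_pmf()]), `n_eff` counts per
#'   bin, `anchor`, plus the converged window shifts `f` (kT) for warm
#'   starts.
#' @export
wham <- function(windows, settings = wham_settings(), anchor_width = 0.5) {
  if (length(windows) < 1) stop("need at least one window")
  samples <- lapply(windows, window_production, settings$equilibration_skip)
  kt <- kt_kj(settings$temperature)
  h <- settings$bin_width
  lo <- floor(min(unlist(samples)) / h) * h
  hi <- ceiling(max(unlist(samples)) / h) * h
  edges <- seq(lo, hi + h / 2, by = h)
  mids <- edges[-1] - h / 2
  nb <- length(mids)
  nw <- length(windows)
  counts <- matrix(vapply(samples, function(s) {
    tabulate(findInterval(s, edges, rightmost.closed = TRUE), nbins = nb)
  }, numeric(nb)), nrow = nb) # nb x nw
  check_window_chain(windows, samples, edges)
  hb <- rowSums(counts)
  ni <- vapply(samples, length, numeric(1))
  # bias factor matrix in kT units: nb x nw
  bias <- matrix(vapply(seq_len(nw), function(i) {
    0.5 * windows[[i]]$force_constant * (mids - windows[[i]]$center)^2 / kt
  }, numeric(nb)), nrow = nb)
  cexp <- exp(-bias)
  occupied <- hb >= max(1, settings$min_counts %||% 5)
  f <- numeric(nw)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    denom <- as.vector(cexp %*% (ni * exp(f)))
    p <- ifelse(denom > 0, hb / denom, 0)
    zf <- as.vector(crossprod(cexp, p))
    f_new <- -log(zf)
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < settings$tolerance) break
    if (iter >= settings$max_iterations) {
      stop(sprintf(
        "WHAM did not converge in %d iterations (residual %.3g kT)",
        iter, delta
      ))
    }
  }
  denom <- as.vector(cexp %*% (ni * exp(f)))
  p <- ifelse(occupied, hb / denom, NA_real_)
  g <- -kt * log(p)
  occ_z <- mids[occupied]
  anchor_bins <- occupied & mids >= max(occ_z) - anchor_width
  # count-weighted anchor: sparse tail bins otherwise dominate the offset
  g <- g - stats::weighted.mean(g[anchor_bins], hb[anchor_bins])
  structure(
    list(bin_centers = mids, z = mids, g = g, g_err = NULL, n_eff = hb,
         f = f, edges = edges,
         anchor = sprintf("zero mean over occupied bins within %.2f nm of the far edge",
                          anchor_width),
         settings = settings),
    class = "pmf_profile"
  )
}

# Error if consecutive windows (by centre) share no occupied bin.
check_window_chain <- function(windows, samples, edges) {
  if (length(windows) < 2) return(invisible(TRUE))
  nb <- length(edges) - 1
  occ <- lapply(samples, function(s) {
    which(tabulate(findInterval(s, edges, rightmost.closed = TRUE),
                   nbins = nb) > 0)
  })
  cen <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(cen)
  for (k in seq_len(length(windows) - 1)) {
    if (!length(intersect(occ[[ord[k]]], occ[[ord[k + 1]]]))) {
      stop(sprintf(
        "disconnected windows: no histogram overlap between centres %.3f and %.3f nm",
        cen[ord[k]], cen[ord[k + 1]]
      ))
    }
  }
  invisible(TRUE)
}

#' Bootstrap errors for a WHAM profile
#'
#' Resamples each window's production samples with replacement (window-level
#' block bootstrap), reruns WHAM warm-started from the converged shifts, and
#' reports the per-bin standard deviation of the anchored profiles.
#'
#' @param windows List of `umbrella_window`.
#' @param settings A `wham_settings` (`n_bootstrap`, `seed`).
#' @param profile Optional previously computed [wham()] result (avoids one
#'   recomputation and fixes the bin grid).
#' @return The `pmf_profile` with `g_err` filled in.
#' @export
bootstrap_pmf <- function(windows, settings = wham_settings(),
                          profile = NULL) {
  if (settings$n_bootstrap < 2) stop("n_bootstrap must be >= 2")
  if (is.null(profile)) profile <- wham(windows, settings)
  reps <- with_seed(settings$seed, {
    lapply(seq_len(settings$n_bootstrap), function(b) {
      wb <- lapply(windows, function(w) {
        s <- window_production(w, settings$equilibration_skip)
        umbrella_window(w$center, w$force_constant,
                        sample(s, length(s), replace = TRUE))
      })
      prof_b <- try(wham(wb, settings), silent = TRUE)
      if (inherits(prof_b, "try-error")) {
        rep(NA_real_, length(profile$g))
      } else {
        # align on bin centres (grids share the same lattice); degenerate
        # single-bin profiles cannot be interpolated
        idx <- match(round(profile$z / settings$bin_width),
                     round(prof_b$z / settings$bin_width))
        prof_b$g[idx]
      }
    })
  })
  gmat <- do.call(cbind, reps)
  profile$g_err <- apply(gmat, 1, stats::sd, na.rm = TRUE)
  profile
}

#' Depth of the free-energy well of a PMF profile
#'
#' With the profile anchored to zero at large separation, the well depth is
#' -min G, and the well position is the bin of the minimum. A profile whose
#' minimum lies in the anchor plateau or is shallower than `min_depth`
#' raises a no-well error.
#'
#' @param profile A `pmf_profile` from [wham()] (or an oracle profile).
#' @param min_depth Minimum depth regarded as a well (kJ/mol), default 1.
#' @return List: `depth` (kJ/mol), `depth_err` (bootstrap error at the
#'   minimum, NA if unavailable), `z_min` (nm).
#' @export
well_depth <- function(profile, min_depth = 1) {
  ok <- is.finite(profile$g)
  if (!any(ok)) stop("no well: profile empty")
  z <- profile$z[ok]
  g <- profile$g[ok]
  imin <- which.min(g)
  depth <- -g[imin]
  if (depth < min_depth || imin == length(g)) {
    stop(sprintf("no well: profile minimum %.3g kJ/mol is not an interior well",
                 depth))
  }
  err <- if (!is.null(profile$g_err)) profile$g_err[ok][imin] else NA_real_
  list(depth = depth, depth_err = err, z_min = z[imin])
}

#' Well-depth difference between two membrane compositions
#'
#' Reports depth(PIP2 membrane) - depth(comparison membrane), with errors
#' propagated in quadrature. This is the PMF-side quantity of the
#' FEP-vs-PMF internal consistency check.
#'
#' @param depth_pip2,depth_ps Well depths in kJ/mol (numbers or
#'   [well_depth()] results).
#' @param err_pip2,err_ps Optional errors (taken from the well-depth objects
#'   when omitted).
#' @return List: `value` (kJ/mol), `err`.
#' @export
delta_pmf <- function(depth_pip2, depth_ps, err_pip2 = NA, err_ps = NA) {
  if (is.list(depth_pip2)) {
    if (is.na(err_pip2)) err_pip2 <- depth_pip2$depth_err
    depth_pip2 <- depth_pip2$depth
  }
  if (is.list(depth_ps)) {
    if (is.na(err_ps)) err_ps <- depth_ps$depth_err
    depth_ps <- depth_ps$depth
  }
  stopifnot(is.finite(depth_pip2), is.finite(depth_ps))
  list(value = depth_pip2 - depth_ps,
       err = sqrt(sum(c(err_pip2, err_ps)^2, na.rm = TRUE)))
}
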