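# Biased-sample generators: harmonic umbrella windows along the COM-height
# reaction coordinate, and alchemical lambda windows for PIP2 -> PC
# head-group transformations. Because the toy model's lipids are ideal, the
# biased marginal distributions are exactly computable, and samples are drawn
# i.i.d. from them (grid inverse-CDF with an independence-Metropolis
# correction where an exact density is available).

#' Umbrella window object
#'
#' @param center Restraint centre (nm).
#' @param force_constant Harmonic force constant (kJ/mol/nm^2).
#' @param samples Reaction-coordinate samples (nm).
#' @param n_equil_skipped Number of leading samples flagged as equilibration.
#' @return Object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant, samples,
                            n_equil_skipped = 0L) {
  if (force_constant < 0) stop("force_constant must be non-negative")
  if (length(samples) < 1) stop("window needs at least one sample")
  structure(
    list(center = center, force_constant = force_constant,
         samples = as.numeric(samples),
         n_equil_skipped = as.integer(n_equil_skipped)),
    class = "umbrella_window"
  )
}

# Effective 1D free-energy profile of the state's system along COM height,
# at the state's (fixed) orientation. Returns splinefun G(z).
effective_pmf_fun <- function(state, params, z_range, step = 0.02, nx = 72) {
  zg <- seq(z_range[1], z_range[2], by = step)
  prof <- if (state$bilayer$mode == "mean-field") {
    analytic_pmf(state$body, state$bilayer, params, zg,
                 orientation = state$body_orientation)
  } else {
    ideal_lipid_pmf(state$body, state$bilayer, params, zg,
                    orientation = quat_to_matrix(state$body_orientation),
                    nx = nx)
  }
  stats::splinefun(prof$z, prof$g, method = "natural")
}

#' Generate umbrella-sampling windows along the COM height
#'
#' For each centre, draws reaction-coordinate samples from the biased
#' distribution p(z) proportional to exp(-(G(z) + k/2 (z - c)^2) / kT), where
#' G is the exact profile of the toy system at the state's orientation. The
#' standard protocol uses centres every 0.05 nm and k = 2000 kJ/mol/nm^2.
#' The first `n_equil` samples of each window are flagged as equilibration
#' (they are skipped by the WHAM stage).
#'
#' @param state `system_state` fixing body, bilayer and orientation.
#' @param params `sim_params`.
#' @param centers Window centres (nm above the plane), non-empty.
#' @param force_constant Restraint force constant (kJ/mol/nm^2), default 2000.
#' @param n_samples Production samples per window.
#' @param n_equil Equilibration samples per window (flagged, not dropped).
#' @param seed Integer seed.
#' @return List of `umbrella_window`. Warns (not errors) if adjacent windows'
#'   sample histograms share no 0.05 nm bin.
#' @export
generate_umbrella_windows <- function(state, params, centers,
                                      force_constant = 2000,
                                      n_samples = 5000, n_equil = 0,
                                      seed = NULL) {
  if (!length(centers)) stop("centers must be non-empty")
  if (force_constant <= 0) stop("force_constant must be positive")
  kt <- kt_kj(params$temperature)
  sd_bias <- sqrt(kt / force_constant)
  pad <- 8 * sd_bias + 0.2
  z_lo <- max(1e-3, min(centers) - pad)
  z_hi <- max(centers) + pad
  gfun <- effective_pmf_fun(state, params, c(z_lo, z_hi))
  with_seed(seed, {
    windows <- lapply(sort(centers), function(cen) {
      lo <- max(z_lo, cen - 7 * sd_bias)
      hi <- min(z_hi, cen + 7 * sd_bias)
      h <- sd_bias / 12
      zg <- seq(lo + h / 2, hi, by = h)
      logp <- -(gfun(zg) + 0.5 * force_constant * (zg - cen)^2) / kt
      s <- sample_density_1d(zg, logp, n_samples + n_equil)
      umbrella_window(cen, force_constant, s, n_equil_skipped = n_equil)
    })
    check_window_overlap(windows)
    windows
  })
}

# Warn when adjacent windows share no occupied 0.05 nm histogram bin.
check_window_overlap <- function(windows, bin_width = 0.05) {
  if (length(windows) < 2) return(invisible(TRUE))
  cen <- vapply(windows, `[[`, numeric(1), "center")
  ord <- order(cen)
  for (i in seq_len(length(windows) - 1)) {
    a <- unique(floor(windows[[ord[i]]]$samples / bin_width))
    b <- unique(floor(windows[[ord[i + 1]]]$samples / bin_width))
    if (!length(intersect(a, b))) {
      warning(sprintf(
        "umbrella windows at %.3f and %.3f nm share no histogram bin",
        cen[ord[i]], cen[ord[i + 1]]
      ))
    }
  }
  invisible(TRUE)
}

#' Alchemical lambda-window set
#'
#' Reduced-potential matrix u[k, l, n]: the energy (in kT) of sample n drawn
#' at state k, re-evaluated at state l.
#'
#' @param lambdas Monotone coupling grid in [0, 1] with endpoints 0 and 1.
#' @param reduced_potentials Array [K, K, n] in kT units.
#' @param samples_per_state Samples per state.
#' @param temperature Kelvin.
#' @param tagged_lipid Index of the transformed lipid (or NA for the free
#'   reference system).
#' @return Object of class `lambda_window_set`.
#' @export
lambda_window_set <- function(lambdas, reduced_potentials, samples_per_state,
                              temperature, tagged_lipid = NA) {
  if (abs(lambdas[1]) > 1e-12 || abs(lambdas[length(lambdas)] - 1) > 1e-12) {
    stop("lambda grid must run from 0 to 1")
  }
  if (is.unsorted(lambdas, strictly = TRUE)) stop("lambdas must be monotone")
  d <- dim(reduced_potentials)
  if (length(d) != 3 || d[1] != length(lambdas) || d[2] != length(lambdas) ||
      d[3] != samples_per_state) {
    stop("reduced-potential matrix dimensions inconsistent with lambda grid")
  }
  structure(
    list(lambdas = lambdas, reduced_potentials = reduced_potentials,
         samples_per_state = samples_per_state, temperature = temperature,
         tagged_lipid = tagged_lipid),
    class = "lambda_window_set"
  )
}

# Interaction energy (kJ/mol) of a full-charge PIP2 head at positions xy
# (m x 2) with the body in the given state.
tagged_lipid_potential <- function(state, params, xy) {
  xyz <- state_bead_coords(state)
  per_lipid_energy(
    xyz, state$body$bead_charges, xy,
    lipid_q = state$bilayer$species_charges[["PIP2"]],
    box_xy = state$bilayer$box_xy, plane_z = state$bilayer$plane_z, params
  )
}

#' Precompute the bound-ensemble grids for alchemical sampling
#'
#' Tabulates the tagged-lipid interaction energy u0(z, xy) of a full-charge
#' PIP2 head with the body at height z (fixed orientation) on a
#' (z, x, y) grid, the exact system profile G(z) of the PIP2 membrane, and
#' the "rest" profile with one PIP2 contribution removed. All upper-leaflet
#' PIP2 are equivalent in the toy (ideal lipids), so one cache serves every
#' transformation.
#'
#' @param state Bound `system_state` (explicit PIP2-containing bilayer);
#'   its orientation defines the bound pose, its COM height is ignored.
#' @param params `sim_params`.
#' @param z_range Bound-ensemble height range (nm), default c(0.6, 2.5).
#' @param nz Height grid points.
#' @param nx xy grid cells per box edge.
#' @return A list used by [generate_lambda_set()] and [fep_dg_exact()].
#' @export
fep_cache <- function(state, params, z_range = c(0.6, 2.5), nz = 50,
                      nx = 90) {
  bil <- state$bilayer
  kt <- kt_kj(params$temperature)
  zg <- seq(z_range[1], z_range[2], length.out = nz)
  gx <- (seq_len(nx) - 0.5) * bil$box_xy[1] / nx
  gy <- (seq_len(nx) - 0.5) * bil$box_xy[2] / nx
  grid_xy <- cbind(rep(gx, times = nx), rep(gy, each = nx))
  u0 <- matrix(0, nz, nx * nx) # u0[z, cell]
  st <- state
  for (iz in seq_len(nz)) {
    st$body_com <- c(state$body_com[1:2], bil$plane_z + zg[iz])
    u0[iz, ] <- tagged_lipid_potential(st, params, grid_xy)
  }
  # one-PIP2 contribution and full/rest profiles on the same z grid
  g1 <- -kt * (apply(-u0 / kt, 1, logsumexp) - log(nx * nx))
  gfull <- ideal_lipid_pmf(state$body, bil, params, zg,
                           orientation = quat_to_matrix(state$body_orientation),
                           nx = 72)$g
  # re-anchor both so the rest profile is consistent (constants cancel in
  # free-energy differences; keep gfull's far-edge anchor)
  grest <- gfull - g1
  list(z = zg, gx = gx, gy = gy, u0 = u0, g_full = gfull, g_rest = grest,
       g_rest_fun = stats::splinefun(zg, grest, method = "natural"),
       state = state, params = params)
}

# Exact u0 at arbitrary (z, x, y) points (m x 3 matrix), via the cache state.
cache_u0_fun <- function(cache) {
  st <- cache$state
  params <- cache$params
  function(pts) {
    vapply(seq_len(nrow(pts)), function(j) {
      s <- st
      s$body_com <- c(st$body_com[1:2], st$bilayer$plane_z + pts[j, 1])
      tagged_lipid_potential(s, params, pts[j, 2:3, drop = FALSE])
    }, numeric(1))
  }
}

#' Generate alchemical lambda windows for one PIP2 -> PC transformation
#'
#' The tagged PIP2 head charge is scaled to (1 - lambda) * Q; at each of the
#' `n_states` coupling values (default 21, i.e. 20 steps) the configuration
#' is sampled from its exact Boltzmann distribution and every sample is
#' re-evaluated at every state to fill the reduced-potential matrix.
#'
#' Two bound-ensemble conventions are supported:
#' * `cache` given (default in [run_fep()]): the configuration is
#'   (body height z, tagged-lipid xy) — the bound body relaxes along z as
#'   the head group is decoupled, as an unrestrained bound protein would.
#' * `cache = NULL`: the body is pinned at the state's pose and only the
#'   tagged lipid's xy is sampled.
#'
#' With `include_protein = FALSE` the companion "free" system (bilayer
#' without bound protein) is generated, for which all interactions vanish.
#'
#' @param state Bound `system_state` (explicit bilayer).
#' @param params `sim_params`.
#' @param n_states Number of lambda states (default 21).
#' @param tagged_lipid Index of the transformed lipid; must be PIP2.
#' @param n_samples Samples per state.
#' @param seed Integer seed.
#' @param include_protein FALSE generates the protein-free reference system.
#' @param nx Sampling-grid cells per box edge (fixed-pose mode).
#' @param cache Optional [fep_cache()] for the z-relaxing bound ensemble.
#' @return A `lambda_window_set`.
#' @export
generate_lambda_set <- function(state, params, n_states = 21, tagged_lipid,
                                n_samples = 500, seed = NULL,
                                include_protein = TRUE, nx = 140,
                                cache = NULL) {
  bil <- state$bilayer
  if (bil$mode != "explicit") stop("lambda windows need an explicit bilayer")
  if (bil$lipid_species[tagged_lipid] != "PIP2") {
    stop("invalid tag: tagged lipid must be PIP2")
  }
  kt <- kt_kj(params$temperature)
  lambdas <- seq(0, 1, length.out = n_states)
  u_red <- array(0, c(n_states, n_states, n_samples))
  if (include_protein && is.null(cache)) {
    gx <- (seq_len(nx) - 0.5) * bil$box_xy[1] / nx
    gy <- (seq_len(nx) - 0.5) * bil$box_xy[2] / nx
    grid_xy <- cbind(rep(gx, times = nx), rep(gy, each = nx))
    u0_grid <- matrix(tagged_lipid_potential(state, params, grid_xy), nx, nx)
    u0_fun <- function(xy) tagged_lipid_potential(state, params, xy)
    with_seed(seed, {
      for (k in seq_len(n_states)) {
        scale_k <- (1 - lambdas[k]) / kt
        pts <- sample_density_2d(
          gx, gy, -scale_k * u0_grid, n_samples,
          logp_fun = function(xy) -scale_k * u0_fun(xy)
        )
        u0_k <- u0_fun(pts)
        # reduced potential of these samples at every state l
        u_red[k, , ] <- outer((1 - lambdas) / kt, u0_k)
      }
    })
  } else if (include_protein) {
    u0_exact <- cache_u0_fun(cache)
    nzc <- length(cache$z)
    ncell <- length(cache$gx) * length(cache$gy)
    hz <- cache$z[2] - cache$z[1]
    hx <- cache$gx[2] - cache$gx[1]
    hy <- cache$gy[2] - cache$gy[1]
    with_seed(seed, {
      for (k in seq_len(n_states)) {
        sc <- (1 - lambdas[k])
        # joint log-density over (z, xy) cells
        logp <- -(cache$g_rest + sc * cache$u0) / kt # nz x ncell
        w <- exp(as.vector(logp) - max(logp))
        cells <- sample.int(length(w), n_samples, replace = TRUE, prob = w)
        izc <- ((cells - 1L) %% nzc) + 1L
        icell <- ((cells - 1L) %/% nzc) + 1L
        ixc <- ((icell - 1L) %% length(cache$gx)) + 1L
        iyc <- ((icell - 1L) %/% length(cache$gx)) + 1L
        pts <- cbind(
          cache$z[izc] + stats::runif(n_samples, -hz / 2, hz / 2),
          cache$gx[ixc] + stats::runif(n_samples, -hx / 2, hx / 2),
          cache$gy[iyc] + stats::runif(n_samples, -hy / 2, hy / 2)
        )
        # independence-MH correction against the exact density
        u0p <- u0_exact(pts)
        grp <- cache$g_rest_fun(pts[, 1])
        lp_prop <- -(grp + sc * u0p) / kt
        lq_prop <- logp[cbind(izc, icell)]
        u0_out <- numeric(n_samples)
        grest_out <- numeric(n_samples)
        acc_lp <- lp_prop[1]
        acc_lq <- lq_prop[1]
        cur_u0 <- u0p[1]
        cur_grest <- grp[1]
        uu <- stats::runif(n_samples)
        for (j in seq_len(n_samples)) {
          if (log(uu[j]) < (lp_prop[j] - acc_lp) + (acc_lq - lq_prop[j])) {
            acc_lp <- lp_prop[j]
            acc_lq <- lq_prop[j]
            cur_u0 <- u0p[j]
            cur_grest <- grp[j]
          }
          u0_out[j] <- cur_u0
          grest_out[j] <- cur_grest
        }
        # reduced potentials at every state l for these samples
        u_red[k, , ] <- (matrix(rep(grest_out, each = n_states), n_states) +
                           outer(1 - lambdas, u0_out)) / kt
      }
    })
  }
  lambda_window_set(lambdas, u_red, n_samples, params$temperature,
                    tagged_lipid = if (include_protein) tagged_lipid else NA)
}

#' Exact z-relaxing transformation free energy (oracle)
#'
#' Quadrature value of the PIP2 -> PC decharging free energy of one tagged
#' lipid with the bound body relaxing along z, matching the ensemble sampled
#' by [generate_lambda_set()] with a cache:
#' dG = -kT log ( int dz exp(-G_rest/kT) / int dz dxy exp(-(G_rest+u0)/kT) ).
#'
#' @param cache A [fep_cache()].
#' @return Free energy in kJ/mol.
#' @export
fep_dg_exact <- function(cache) {
  kt <- kt_kj(cache$params$temperature)
  ncell <- ncol(cache$u0)
  l_end <- logsumexp(-cache$g_rest / kt) + log(ncell)
  l_start <- logsumexp(as.vector(-(cache$g_rest + cache$u0) / kt))
  -kt * (l_end - l_start)
}

#' Exact transformation free energy of a tagged lipid (oracle)
#'
#' Quadrature value of the PIP2 -> PC decharging free energy of the tagged
#' lipid in the field of the bound body:
#' dG = kT log < exp(-u0(xy)/kT) >_box. Used as ground truth for the
#' BAR/MBAR estimators.
#'
#' @param state Bound `system_state`.
#' @param params `sim_params`.
#' @param nx Quadrature cells per box edge.
#' @return Free energy in kJ/mol (positive when the interaction is
#'   favourable, i.e. removing it costs free energy).
#' @export
tagged_lipid_dg_exact <- function(state, params, nx = 280) {
  bil <- state$bilayer
  gx <- (seq_len(nx) - 0.5) * bil$box_xy[1] / nx
  gy <- (seq_len(nx) - 0.5) * bil$box_xy[2] / nx
  grid_xy <- cbind(rep(gx, times = nx), rep(gy, each = nx))
  kt <- kt_kj(params$temperature)
  u0 <- tagged_lipid_potential(state, params, grid_xy)
  kt * (logsumexp(-u0 / kt) - log(length(u0)))
}
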