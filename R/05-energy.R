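# Potential energy of the toy model and its analytic free-energy oracles.
#
# Interactions:
#  * screened Coulomb between body beads and lipid head charges (explicit
#    mode), with xy minimum image and lipid z at the bilayer plane; pair
#    distances are capped below at core_radius (bead excluded volume);
#  * or, in mean-field mode, the closed-form energy of each bead above a
#    uniformly charged plane: U_i(z) = 2*pi*sigma*q_i*B*lambda_D*exp(-z/lambda_D);
#  * a soft exponential wall that keeps beads above the plane;
#  * optionally a harmonic upper wall on the COM height (encounter runs) and
#    a harmonic restraint on the COM height (umbrella sampling).

# Per-lipid interaction energy with a set of beads (kJ/mol).
# bead_xyz: n x 3, lipid_xy: m x 2; lipid z at plane_z. Returns length-m.
per_lipid_energy <- function(bead_xyz, bead_charges, lipid_xy, lipid_q,
                             box_xy, plane_z, params) {
  active <- which(bead_charges != 0)
  m <- nrow(lipid_xy)
  out <- numeric(m)
  if (!length(active) || !m) {
    return(out)
  }
  B <- params$bjerrum_prefactor
  lam <- params$debye_length
  core <- params$core_radius
  for (i in active) {
    dx <- min_image(lipid_xy[, 1] - bead_xyz[i, 1], box_xy[1])
    dy <- min_image(lipid_xy[, 2] - bead_xyz[i, 2], box_xy[2])
    dz <- plane_z - bead_xyz[i, 3]
    r <- sqrt(dx * dx + dy * dy + dz * dz)
    out <- out + bead_charges[i] * B * exp(-r / lam) / pmax(r, core)
  }
  out * lipid_q
}

# Mean-field per-bead electrostatic energy (kJ/mol), vector over beads.
mean_field_energy <- function(z_beads, bead_charges, sigma, params) {
  pref <- 2 * pi * sigma * params$bjerrum_prefactor * params$debye_length
  pref * bead_charges * exp(-z_beads / params$debye_length)
}

# Soft exponential plane repulsion per bead (kJ/mol).
wall_energy <- function(z_beads, params) {
  params$wall_stiffness * exp(-z_beads / params$wall_decay)
}

#' Potential energy of a system state
#'
#' Sum of bead-lipid screened-Coulomb interactions (explicit mode) or the
#' mean-field charged-plane energy, plus the soft plane repulsion. With
#' `lambda` and `tagged_lipid` set, the tagged lipid's head charge is scaled
#' to (1 - lambda) * Q, the linear alchemical coupling used for
#' PIP2-to-PC head-group transformations.
#'
#' @param state A `system_state`.
#' @param params A `sim_params`.
#' @param lambda Optional alchemical coupling in [0, 1].
#' @param tagged_lipid Optional index of the transformed lipid
#'   (must be a PIP2 when `lambda` is used).
#' @param upper_wall Apply the harmonic upper wall on COM height.
#' @return Energy in kJ/mol.
#' @export
potential_energy <- function(state, params, lambda = NULL, tagged_lipid = NULL,
                             upper_wall = FALSE) {
  if (!is.null(lambda) && (lambda < 0 || lambda > 1)) {
    stop("lambda must lie in [0, 1]")
  }
  bil <- state$bilayer
  xyz <- state_bead_coords(state)
  zrel <- xyz[, 3] - bil$plane_z
  u <- sum(wall_energy(zrel, params))
  if (bil$mode == "mean-field") {
    u <- u + sum(mean_field_energy(zrel, state$body$bead_charges,
                                   surface_charge_density(bil), params))
  } else {
    lq <- lipid_charges(bil)
    if (!is.null(lambda)) {
      if (is.null(tagged_lipid)) stop("tagged_lipid required with lambda")
      if (bil$lipid_species[tagged_lipid] != "PIP2") {
        stop("invalid tag: tagged lipid must be PIP2")
      }
      lq[tagged_lipid] <- (1 - lambda) * lq[tagged_lipid]
    }
    u <- u + sum(per_lipid_energy(xyz, state$body$bead_charges, bil$lipid_xy,
                                  lq, bil$box_xy, bil$plane_z, params))
  }
  if (upper_wall) {
    d <- state$body_com[3] - bil$plane_z
    if (d > params$upper_wall_distance) {
      u <- u + 0.5 * params$upper_wall_k * (d - params$upper_wall_distance)^2
    }
  }
  u
}

# Forces and torque for the Langevin integrator.
# Returns list(f_com, torque, f_lipids [m x 2]).
system_forces <- function(state, params, upper_wall = FALSE, restraint = NULL) {
  bil <- state$bilayer
  body <- state$body
  xyz <- state_bead_coords(state)
  n <- nrow(xyz)
  zrel <- xyz[, 3] - bil$plane_z
  f_beads <- matrix(0, n, 3)
  # plane wall: upward force on every bead
  f_beads[, 3] <- wall_energy(zrel, params) / params$wall_decay
  m <- if (is.null(bil$lipid_xy)) 0L else nrow(bil$lipid_xy)
  f_lip <- if (m) matrix(0, m, 2) else NULL
  if (bil$mode == "mean-field") {
    umf <- mean_field_energy(zrel, body$bead_charges,
                             surface_charge_density(bil), params)
    f_beads[, 3] <- f_beads[, 3] + umf / params$debye_length
  } else if (m) {
    B <- params$bjerrum_prefactor
    lam <- params$debye_length
    core <- params$core_radius
    lq <- lipid_charges(bil)
    active <- which(body$bead_charges != 0)
    for (i in active) {
      dx <- min_image(bil$lipid_xy[, 1] - xyz[i, 1], bil$box_xy[1])
      dy <- min_image(bil$lipid_xy[, 2] - xyz[i, 2], bil$box_xy[2])
      dz <- bil$plane_z - xyz[i, 3]
      r2 <- dx * dx + dy * dy + dz * dz
      r <- sqrt(r2)
      reff <- pmax(r, core)
      u <- body$bead_charges[i] * lq * B * exp(-r / lam) / reff
      # du/dr (capped region: only the screening factor varies)
      dudr <- ifelse(r > core, -u * (1 / lam + 1 / r), -u / lam)
      fmag <- -dudr / pmax(r, 1e-12) # force along +dr acts on the lipid
      fx <- fmag * dx
      fy <- fmag * dy
      fz <- fmag * dz
      f_lip[, 1] <- f_lip[, 1] + fx
      f_lip[, 2] <- f_lip[, 2] + fy
      f_beads[i, 1] <- f_beads[i, 1] - sum(fx)
      f_beads[i, 2] <- f_beads[i, 2] - sum(fy)
      f_beads[i, 3] <- f_beads[i, 3] - sum(fz)
    }
  }
  f_com <- colSums(f_beads)
  d <- state$body_com[3] - bil$plane_z
  if (upper_wall && d > params$upper_wall_distance) {
    f_com[3] <- f_com[3] - params$upper_wall_k * (d - params$upper_wall_distance)
  }
  if (!is.null(restraint)) {
    f_com[3] <- f_com[3] - restraint$k * (d - restraint$center)
  }
  arm <- sweep(xyz, 2, state$body_com)
  torque <- c(
    sum(arm[, 2] * f_beads[, 3] - arm[, 3] * f_beads[, 2]),
    sum(arm[, 3] * f_beads[, 1] - arm[, 1] * f_beads[, 3]),
    sum(arm[, 1] * f_beads[, 2] - arm[, 2] * f_beads[, 1])
  )
  list(f_com = f_com, torque = torque, f_lipids = f_lip)
}

# Near-uniform unit vectors on the sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Analytic mean-field potential of mean force (oracle)
#'
#' Closed-form free-energy profile of the body COM height above a mean-field
#' charged plane. With `orientation` fixed, G(z) is simply the potential
#' energy of the rigid body at that height. With `orientation = NULL` the
#' orientational partition function is integrated numerically over the sphere
#' of body axes (Fibonacci quadrature with `n_orient` nodes):
#' G(z) = -kT log < exp(-U(z, a)/kT) >_a. The profile is anchored to zero at
#' the largest grid height.
#'
#' @param body A `protein_body`.
#' @param bilayer A mean-field `bilayer_model`.
#' @param params A `sim_params`.
#' @param z_grid Increasing COM heights above the plane (nm).
#' @param orientation Optional fixed orientation (3x3 rotation matrix or
#'   quaternion); NULL averages over orientations.
#' @param n_orient Number of orientation quadrature nodes.
#' @return List with `z`, `g` (kJ/mol) and `anchor` description,
#'   class `pmf_profile`.
#' @export
analytic_pmf <- function(body, bilayer, params, z_grid,
                         orientation = NULL, n_orient = 2000) {
  if (bilayer$mode != "mean-field") stop("analytic_pmf needs mean-field mode")
  if (is.unsorted(z_grid, strictly = TRUE)) stop("z_grid must be increasing")
  sigma <- surface_charge_density(bilayer)
  kt <- kt_kj(params$temperature)
  q <- body$bead_charges
  u_fixed <- function(dz_beads) {
    # dz_beads: bead z-offsets for one orientation; returns U(z) over z_grid
    zb <- outer(z_grid, dz_beads, "+") # nz x nbead
    colSums(t(exp(-zb / params$debye_length)) *
              (2 * pi * sigma * params$bjerrum_prefactor *
                 params$debye_length * q)) +
      colSums(t(exp(-zb / params$wall_decay)) * params$wall_stiffness)
  }
  if (!is.null(orientation)) {
    R <- if (is.matrix(orientation)) orientation else quat_to_matrix(orientation)
    dz <- as.numeric(body$bead_positions %*% R[3, ])
    g <- u_fixed(dz)
  } else {
    axes <- fibonacci_sphere(n_orient)
    lw <- matrix(0, length(z_grid), n_orient)
    for (k in seq_len(n_orient)) {
      dz <- as.numeric(body$bead_positions %*% axes[k, ])
      lw[, k] <- -u_fixed(dz) / kt
    }
    g <- -kt * (logsumexp_rows(lw) - log(n_orient))
  }
  g <- g - g[length(g)]
  structure(
    list(z = z_grid, g = g, g_err = NULL,
         anchor = "zero at largest grid height"),
    class = "pmf_profile"
  )
}

#' Exact PMF of the explicit ideal-lipid model (oracle)
#'
#' In the toy model lipids do not interact with each other, so the exact
#' free-energy profile of the body COM height is a sum of independent
#' single-lipid contributions, each a 2D partition-function integral over the
#' periodic box evaluated by midpoint quadrature:
#' G(z) = wall(z) + sum_s n_s * (-kT) log < exp(-u_s(z, xy)/kT) >_box.
#' Used as ground truth for umbrella sampling / WHAM and for the
#' free-energy-perturbation consistency checks.
#'
#' @param body A `protein_body`.
#' @param bilayer An explicit `bilayer_model` (only counts/charges are used).
#' @param params A `sim_params`.
#' @param z_grid Increasing COM heights above the plane (nm).
#' @param orientation Fixed orientation (3x3 matrix or quaternion).
#' @param nx Quadrature cells per box edge.
#' @return A `pmf_profile` list anchored to zero at the largest grid height.
#' @export
ideal_lipid_pmf <- function(body, bilayer, params, z_grid,
                            orientation = diag(3), nx = 72) {
  if (is.unsorted(z_grid, strictly = TRUE)) stop("z_grid must be increasing")
  R <- if (is.matrix(orientation)) orientation else quat_to_matrix(orientation)
  pos <- body$bead_positions %*% t(R) # body at COM origin
  kt <- kt_kj(params$temperature)
  box <- bilayer$box_xy
  gx <- (seq_len(nx) - 0.5) * box[1] / nx
  gy <- (seq_len(nx) - 0.5) * box[2] / nx
  cells <- cbind(rep(gx, times = nx), rep(gy, each = nx))
  # Body xy at box centre; offsets via minimum image so placement is moot.
  cx <- box / 2
  g <- numeric(length(z_grid))
  active <- which(body$bead_charges != 0)
  dx2 <- lapply(active, function(i) {
    dx <- min_image(cells[, 1] - (cx[1] + pos[i, 1]), box[1])
    dy <- min_image(cells[, 2] - (cx[2] + pos[i, 2]), box[2])
    dx * dx + dy * dy
  })
  for (iz in seq_along(z_grid)) {
    zb <- z_grid[iz] + pos[, 3] # bead heights above the plane
    # interaction of a unit (+1 e) head charge with all beads, per cell
    u_unit <- numeric(nrow(cells))
    for (j in seq_along(active)) {
      i <- active[j]
      r <- sqrt(dx2[[j]] + zb[i]^2)
      u_unit <- u_unit + body$bead_charges[i] * params$bjerrum_prefactor *
        exp(-r / params$debye_length) / pmax(r, params$core_radius)
    }
    gz <- sum(wall_energy(zb, params))
    for (s in names(bilayer$species_counts)) {
      nsp <- bilayer$species_counts[[s]]
      qs <- bilayer$species_charges[[s]]
      if (nsp == 0 || qs == 0) next
      lw <- -qs * u_unit / kt
      gz <- gz - nsp * kt * (logsumexp(lw) - log(length(lw)))
    }
    g[iz] <- gz
  }
  g <- g - g[length(g)]
  structure(
    list(z = z_grid, g = g, g_err = NULL,
         anchor = "zero at largest grid height"),
    class = "pmf_profile"
  )
}
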