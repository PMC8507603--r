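# Simulation parameters and system state (pose + bilayer).

#' Simulation parameters for the toy membrane-binding model
#'
#' Units: nm, ps, kJ/mol, Kelvin, elementary charges.
#'
#' Electrostatics are screened Coulomb
#' u(r) = q Q * bjerrum_prefactor * exp(-r / debye_length) / max(r, core_radius);
#' the short-range cap at `core_radius` stands in for the excluded volume of
#' coarse-grained beads. A soft exponential wall
#' wall_stiffness * exp(-(z - plane_z) / wall_decay) per bead keeps the body
#' above the bilayer plane, and an optional harmonic upper wall at
#' `upper_wall_distance` (default 7 nm, matching the encounter-simulation
#' restraint) confines the unbound body.
#'
#' @param temperature Kelvin (default 323).
#' @param timestep Integration step in ps.
#' @param diff_trans Translational diffusion coefficient of the body
#'   (nm^2/ps).
#' @param diff_rot Rotational diffusion coefficient (rad^2/ps).
#' @param diff_lipid Lipid 2D diffusion coefficient (nm^2/ps).
#' @param debye_length Electrostatic screening length (nm).
#' @param bjerrum_prefactor Coulomb prefactor in kJ/mol nm e^-2;
#'   default 138.935 / 100, an effective interfacial dielectric chosen so
#'   that bound-state per-PIP2 interaction free energies sit on the 4-21
#'   kJ/mol scale seen in coarse-grained protein-PIP2 free-energy
#'   calculations.
#' @param core_radius Short-range cap on pair distances (nm).
#' @param wall_stiffness Amplitude of the exponential plane repulsion
#'   (kJ/mol per bead).
#' @param wall_decay Decay length of the plane repulsion (nm).
#' @param upper_wall_distance COM height of the harmonic upper wall (nm).
#' @param upper_wall_k Upper-wall force constant (kJ/mol/nm^2).
#' @param seed Default RNG seed carried with the parameters.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(temperature = 323,
                       timestep = 0.05,
                       diff_trans = 0.01,
                       diff_rot = 0.01,
                       diff_lipid = 0.01,
                       debye_length = 1.1,
                       bjerrum_prefactor = 138.935 / 100,
                       core_radius = 0.47,
                       wall_stiffness = 200,
                       wall_decay = 0.05,
                       upper_wall_distance = 7,
                       upper_wall_k = 50,
                       seed = NULL) {
  p <- list(
    temperature = temperature, timestep = timestep,
    diff_trans = diff_trans, diff_rot = diff_rot, diff_lipid = diff_lipid,
    debye_length = debye_length, bjerrum_prefactor = bjerrum_prefactor,
    core_radius = core_radius,
    wall_stiffness = wall_stiffness, wall_decay = wall_decay,
    upper_wall_distance = upper_wall_distance, upper_wall_k = upper_wall_k,
    seed = seed
  )
  num <- unlist(p[setdiff(names(p), "seed")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all sim_params values must be positive and finite")
  }
  structure(p, class = "sim_params")
}

#' System state: rigid-body pose above a bilayer
#'
#' @param body A `protein_body`.
#' @param bilayer A `bilayer_model`.
#' @param body_com Length-3 COM position (nm).
#' @param body_orientation Unit quaternion c(w,x,y,z) or 3x3 rotation matrix.
#' @param time Time stamp in ps.
#' @return Object of class `system_state`.
#' @export
system_state <- function(body, bilayer, body_com,
                         body_orientation = c(1, 0, 0, 0), time = 0) {
  stopifnot(inherits(body, "protein_body"), inherits(bilayer, "bilayer_model"))
  if (is.matrix(body_orientation)) {
    body_orientation <- matrix_to_quat(body_orientation)
  }
  if (abs(sqrt(sum(body_orientation^2)) - 1) > 1e-9) {
    stop("orientation quaternion must be normalized")
  }
  structure(
    list(
      body = body, bilayer = bilayer,
      body_com = as.numeric(body_com),
      body_orientation = as.numeric(body_orientation),
      time = time
    ),
    class = "system_state"
  )
}

#' Initialise an encounter simulation state
#'
#' The body is given a uniformly random orientation on the rotation group and
#' placed so that its lowest bead sits exactly `min_separation` above the
#' bilayer plane (default 4.4 nm, outside the interaction range), centred in
#' xy. This mirrors the unbiased random-rotation initial placement of
#' ensemble encounter simulations.
#'
#' @param body A `protein_body`.
#' @param bilayer A `bilayer_model`.
#' @param min_separation Minimum bead-plane distance (nm), default 4.4.
#' @param seed Optional integer seed.
#' @return A `system_state`.
#' @export
init_system <- function(body, bilayer, min_separation = 4.4, seed = NULL) {
  if (min_separation <= 0) stop("min_separation must be positive")
  q <- with_seed(seed, as.numeric(random_quaternion(1)))
  R <- quat_to_matrix(q)
  zmin_body <- min((body$bead_positions %*% t(R))[, 3])
  com <- c(bilayer$box_xy / 2, bilayer$plane_z + min_separation - zmin_body)
  system_state(body, bilayer, com, q, time = 0)
}

# Lab-frame bead coordinates of a state.
state_bead_coords <- function(state) {
  body_lab_coords(state$body, quat_to_matrix(state$body_orientation),
                  state$body_com)
}
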