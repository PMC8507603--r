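# Overdamped Langevin (Brownian) dynamics of the rigid body and, in explicit
# mode, of the 2D lipid head groups. This replaces a molecular-dynamics
# engine while preserving the ensemble statistics the downstream analyses
# consume: encounter, binding, orientational relaxation, lipid clustering.

#' Trajectory container
#'
#' Time series of rigid-body pose (COM + orientation quaternion) and, for
#' explicit bilayers, upper-leaflet lipid positions per frame. Composition is
#' constant across frames.
#'
#' @param times Frame times (ps), strictly increasing.
#' @param com n x 3 matrix of COM positions.
#' @param quat n x 4 matrix of orientation quaternions.
#' @param body The `protein_body`.
#' @param bilayer The `bilayer_model` (positions = last frame).
#' @param lipid_xy Optional array [frame, lipid, 2] of head-group positions.
#' @param frame_interval Time between frames (ps).
#' @param metadata Named list (membrane label, repeat index, seed, ...).
#' @return Object of class `membind_trajectory`.
#' @export
trajectory <- function(times, com, quat, body, bilayer, lipid_xy = NULL,
                       frame_interval = NULL, metadata = list()) {
  stopifnot(length(times) == nrow(com), nrow(com) == nrow(quat))
  if (is.unsorted(times, strictly = TRUE)) {
    stop("frame times must be strictly increasing")
  }
  structure(
    list(
      times = as.numeric(times), com = com, quat = quat,
      body = body, bilayer = bilayer, lipid_xy = lipid_xy,
      frame_interval = frame_interval %||% (if (length(times) > 1)
        times[2] - times[1] else NA_real_),
      metadata = metadata
    ),
    class = "membind_trajectory"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.membind_trajectory <- function(x, ...) {
  cat(
    "membind_trajectory:", length(x$times), "frames,",
    signif(diff(range(x$times)), 4), "ps,",
    if (is.null(x$lipid_xy)) "mean-field bilayer" else
      paste0(dim(x$lipid_xy)[2], " explicit lipids"), "\n"
  )
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

# Rotation matrix of frame i.
frame_rotation <- function(traj, i) quat_to_matrix(traj$quat[i, ])

# Lab-frame bead coordinates of frame i.
frame_bead_coords <- function(traj, i) {
  body_lab_coords(traj$body, frame_rotation(traj, i), traj$com[i, ])
}

#' Run Brownian dynamics of the body above the bilayer
#'
#' Euler-Maruyama integration of overdamped Langevin dynamics: the COM
#' diffuses in 3D with drift from the net force, the orientation diffuses on
#' the rotation group with drift from the torque (applied as small lab-frame
#' rotations), and in explicit mode lipids diffuse in the xy plane with drift
#' from the bead-lipid forces, wrapped periodically. Reproducible from
#' `seed`; with zero temperature limits this reduces to steepest descent.
#'
#' @param state Initial `system_state`.
#' @param params `sim_params`.
#' @param n_steps Number of integration steps (>= 1).
#' @param record_every Record a frame every this many steps.
#' @param upper_wall Apply the harmonic upper wall (encounter runs).
#' @param restraint Optional list(k, center): harmonic restraint on COM
#'   height above the plane (umbrella-style biased runs).
#' @param move_body Integrate body COM/orientation (set FALSE to freeze the
#'   bound pose while lipids equilibrate).
#' @param move_orientation Integrate the orientation (set FALSE to lock the
#'   orientation while the COM diffuses).
#' @param move_lipids Integrate explicit lipids.
#' @param seed Integer seed.
#' @param metadata Named list stored with the trajectory.
#' @return A `membind_trajectory` (first frame = initial state).
#' @export
simulate_bd <- function(state, params, n_steps, record_every = 1,
                        upper_wall = FALSE, restraint = NULL,
                        move_body = TRUE, move_orientation = TRUE,
                        move_lipids = TRUE,
                        seed = NULL, metadata = list()) {
  stopifnot(n_steps >= 1)
  with_seed(seed %||% params$seed, {
    kt <- kt_kj(params$temperature)
    dt <- params$timestep
    bil <- state$bilayer
    body <- state$body
    explicit <- bil$mode == "explicit" && !is.null(bil$lipid_xy)
    m <- if (explicit) nrow(bil$lipid_xy) else 0L
    mob_t <- params$diff_trans / kt * dt
    mob_r <- params$diff_rot / kt * dt
    mob_l <- params$diff_lipid / kt * dt
    sd_t <- sqrt(2 * params$diff_trans * dt)
    sd_r <- sqrt(2 * params$diff_rot * dt)
    sd_l <- sqrt(2 * params$diff_lipid * dt)
    max_arm <- max(sqrt(rowSums(body$bead_positions^2)))
    drift_cap <- 0.5 * params$debye_length
    # precomputed constants for the inlined force kernel
    pos0 <- body$bead_positions
    qb <- body$bead_charges
    nb <- nrow(pos0)
    active <- which(qb != 0)
    plane <- bil$plane_z
    boxx <- bil$box_xy[1]
    boxy <- bil$box_xy[2]
    w_amp <- params$wall_stiffness
    w_dec <- params$wall_decay
    lam <- params$debye_length
    bpre <- params$bjerrum_prefactor
    core <- params$core_radius
    sigma <- if (bil$mode == "mean-field") surface_charge_density(bil) else 0
    mf_pref <- 2 * pi * sigma * bpre * lam * qb
    lq <- if (explicit) lipid_charges(bil) else NULL

    nrec <- n_steps %/% record_every
    times <- state$time + dt * record_every * seq_len(nrec)
    com_rec <- matrix(0, nrec + 1L, 3)
    quat_rec <- matrix(0, nrec + 1L, 4)
    lip_rec <- if (explicit) array(0, c(nrec + 1L, m, 2)) else NULL
    com <- state$body_com
    q <- state$body_orientation
    lip <- if (explicit) bil$lipid_xy else NULL
    com_rec[1, ] <- com
    quat_rec[1, ] <- q
    if (explicit) lip_rec[1, , ] <- lip
    irec <- 1L
    for (step in seq_len(n_steps)) {
      R <- quat_to_matrix(q)
      xyz <- pos0 %*% t(R)
      xyz[, 1] <- xyz[, 1] + com[1]
      xyz[, 2] <- xyz[, 2] + com[2]
      xyz[, 3] <- xyz[, 3] + com[3]
      zrel <- xyz[, 3] - plane
      fb <- matrix(0, nb, 3)
      fb[, 3] <- (w_amp / w_dec) * exp(-zrel / w_dec)
      if (!explicit) {
        fb[, 3] <- fb[, 3] + (mf_pref / lam) * exp(-zrel / lam)
        f_lip <- NULL
      } else {
        f_lip <- matrix(0, m, 2)
        for (i in active) {
          dx <- lip[, 1] - xyz[i, 1]
          dx <- dx - boxx * round(dx / boxx)
          dy <- lip[, 2] - xyz[i, 2]
          dy <- dy - boxy * round(dy / boxy)
          dz <- plane - xyz[i, 3]
          r <- sqrt(dx * dx + dy * dy + dz * dz)
          u <- (qb[i] * bpre) * lq * exp(-r / lam) / pmax(r, core)
          dudr <- ifelse(r > core, -u * (1 / lam + 1 / r), -u / lam)
          fmag <- -dudr / pmax(r, 1e-12)
          fx <- fmag * dx
          fy <- fmag * dy
          f_lip[, 1] <- f_lip[, 1] + fx
          f_lip[, 2] <- f_lip[, 2] + fy
          fb[i, ] <- fb[i, ] - c(sum(fx), sum(fy), sum(fmag * dz))
        }
      }
      f_com <- colSums(fb)
      d <- com[3] - plane
      if (upper_wall && d > params$upper_wall_distance) {
        f_com[3] <- f_com[3] - params$upper_wall_k *
          (d - params$upper_wall_distance)
      }
      if (!is.null(restraint)) {
        f_com[3] <- f_com[3] - restraint$k * (d - restraint$center)
      }
      if (move_body) {
        arm1 <- xyz[, 1] - com[1]
        arm2 <- xyz[, 2] - com[2]
        arm3 <- xyz[, 3] - com[3]
        torque <- c(sum(arm2 * fb[, 3] - arm3 * fb[, 2]),
                    sum(arm3 * fb[, 1] - arm1 * fb[, 3]),
                    sum(arm1 * fb[, 2] - arm2 * fb[, 1]))
        drift <- mob_t * f_com
        rot_drift <- mob_r * torque
        if (sqrt(sum(drift^2)) + max_arm * sqrt(sum(rot_drift^2)) > drift_cap) {
          stop("integration instability: drift step exceeds 0.5 * debye_length; ",
               "reduce timestep")
        }
        com <- com + drift + sd_t * stats::rnorm(3)
        if (move_orientation) {
          q <- quat_normalize(
            quat_multiply(quat_from_rotvec(rot_drift + sd_r * stats::rnorm(3)),
                          q)
          )
        }
      }
      if (explicit && move_lipids) {
        lip <- lip + mob_l * f_lip +
          matrix(sd_l * stats::rnorm(2 * m), m, 2)
        lip[, 1] <- lip[, 1] - boxx * floor(lip[, 1] / boxx)
        lip[, 2] <- lip[, 2] - boxy * floor(lip[, 2] / boxy)
      }
      if (step %% record_every == 0L) {
        irec <- irec + 1L
        com_rec[irec, ] <- com
        quat_rec[irec, ] <- q
        if (explicit) lip_rec[irec, , ] <- lip
      }
    }
    final_bil <- bil
    if (explicit) final_bil$lipid_xy <- lip
    trajectory(
      times = c(state$time, times), com = com_rec, quat = quat_rec,
      body = state$body, bilayer = final_bil, lipid_xy = lip_rec,
      frame_interval = dt * record_every,
      metadata = c(metadata, list(seed = seed %||% params$seed))
    )
  })
}

#' Simulate an encounter ensemble
#'
#' Runs `n_repeats` independent encounter simulations from random initial
#' orientations at the standard initial separation, one seed per repeat
#' (`seed_base + repeat index`), mirroring replicated coarse-grained
#' encounter ensembles (default 25 repeats).
#'
#' @param body `protein_body`.
#' @param bilayer `bilayer_model`.
#' @param params `sim_params`.
#' @param n_repeats Number of repeats (default 25).
#' @param n_steps Steps per repeat.
#' @param record_every Frame recording stride.
#' @param min_separation Initial minimum bead-plane distance (nm, default 4.4).
#' @param seed_base Base seed; repeat i uses seed_base + i.
#' @param upper_wall Apply the harmonic upper wall (default TRUE, as in
#'   encounter runs).
#' @param membrane_label Stored in each trajectory's metadata.
#' @return List of `membind_trajectory`.
#' @export
simulate_ensemble <- function(body, bilayer, params, n_repeats = 25,
                              n_steps = 2000, record_every = 10,
                              min_separation = 4.4, seed_base = 1,
                              upper_wall = TRUE, membrane_label = "") {
  lapply(seq_len(n_repeats), function(i) {
    st <- init_system(body, bilayer, min_separation, seed = seed_base + i)
    simulate_bd(
      st, params, n_steps, record_every,
      upper_wall = upper_wall, seed = seed_base + i,
      metadata = list(membrane = membrane_label, repeat_index = i)
    )
  })
}
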