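# Orientation analysis: least-squares rotation matrices, the Rzz statistic,
# distance/orientation density maps, binding-mode detection and scoring, and
# classification of refinement trajectories.

#' Least-squares rotation between two bead configurations (Kabsch)
#'
#' Removes the centres of mass and returns the proper rotation R minimising
#' the RMSD between `coords` and `R %*% ref_coords` (i.e. coords ~ R ref).
#'
#' @param ref_coords n x 3 reference coordinates (n >= 3, non-collinear).
#' @param coords n x 3 coordinates with the same bead order.
#' @return 3x3 proper rotation matrix (det +1 enforced).
#' @export
rotation_matrix <- function(ref_coords, coords) {
  ref_coords <- as.matrix(ref_coords)
  coords <- as.matrix(coords)
  if (nrow(ref_coords) != nrow(coords)) stop("bead count mismatch")
  if (nrow(ref_coords) < 3) stop("need at least 3 beads")
  a <- sweep(ref_coords, 2, colMeans(ref_coords))
  b <- sweep(coords, 2, colMeans(coords))
  sv <- svd(a)$d
  if (sv[2] < 1e-9 * max(sv[1], 1e-300)) {
    stop("degenerate geometry: reference beads are collinear")
  }
  h <- crossprod(a, b) # sum_i a_i b_i^T
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Orientation series object
#'
#' @param times Frame times (ps).
#' @param rzz Rzz values in [-1, 1].
#' @param reference_id Identifier of the reference structure/frame.
#' @return Object of class `orientation_series`.
#' @export
orientation_series <- function(times, rzz, reference_id = "reference") {
  stopifnot(length(times) == length(rzz))
  if (any(abs(rzz) > 1 + 1e-9)) stop("|rzz| must not exceed 1")
  structure(list(times = as.numeric(times),
                 rzz = pmin(1, pmax(-1, as.numeric(rzz))),
                 reference_id = reference_id),
            class = "orientation_series")
}

#' Rzz orientation statistic along a trajectory
#'
#' Per frame, the zz element of the least-squares rotation matrix relating
#' the reference bead coordinates to the frame's bead coordinates. Rzz = 1
#' means the orientation along z matches the reference; Rzz = -1 means the
#' body is flipped 180 degrees about an in-plane axis. Because only the zz
#' element is used, the statistic is invariant to any additional rotation
#' about z applied before or after (the bilayer is isotropic in xy), so no
#' xy pre-fitting is needed for a rigid body.
#'
#' @param traj A `membind_trajectory`.
#' @param reference n x 3 reference bead coordinates (same bead order), or a
#'   list(traj =, frame =) pair.
#' @param reference_id Label stored in the result.
#' @return An `orientation_series`.
#' @export
rzz_series <- function(traj, reference, reference_id = "reference") {
  ref <- if (is.list(reference) && !is.null(reference$traj)) {
    frame_bead_coords(reference$traj, reference$frame)
  } else {
    as.matrix(reference)
  }
  if (nrow(ref) != nrow(traj$body$bead_positions)) {
    stop("reference has different bead topology")
  }
  nf <- n_frames(traj)
  rzz <- numeric(nf)
  for (i in seq_len(nf)) {
    rzz[i] <- rotation_matrix(ref, frame_bead_coords(traj, i))[3, 3]
  }
  orientation_series(traj$times, rzz, reference_id)
}

#' Default reference structure: last frame of the first repeat
#'
#' @param trajs List of `membind_trajectory` (an ensemble).
#' @return n x 3 bead coordinates of the last frame of the first trajectory.
#' @export
reference_from_ensemble <- function(trajs) {
  t1 <- trajs[[1]]
  frame_bead_coords(t1, n_frames(t1))
}

#' COM height distance series
#'
#' Per frame, the z component of the vector from the bilayer plane to the
#' body centre of mass.
#'
#' @param traj A `membind_trajectory`.
#' @return A `distance_series` of kind "com-z".
#' @export
com_z_distance_series <- function(traj) {
  distance_series(traj$times, traj$com[, 3] - traj$bilayer$plane_z,
                  kind = "com-z")
}

#' Pool an ensemble into (distance, Rzz) observations
#'
#' @param trajs List of `membind_trajectory`.
#' @param reference Reference bead coordinates for [rzz_series()].
#' @param distance "com-z" (default) or "min-bead-pair".
#' @return data.frame with columns traj, frame, time, distance, rzz.
#' @export
pose_ensemble <- function(trajs, reference, distance = c("com-z",
                                                         "min-bead-pair")) {
  distance <- match.arg(distance)
  do.call(rbind, lapply(seq_along(trajs), function(j) {
    tr <- trajs[[j]]
    ds <- if (distance == "com-z") com_z_distance_series(tr) else
      min_distance_series(tr)
    os <- rzz_series(tr, reference)
    data.frame(traj = j, frame = seq_len(n_frames(tr)), time = tr$times,
               distance = ds$values, rzz = os$rzz)
  }))
}

#' 2D (distance, Rzz) occupancy density map
#'
#' Pooled histogram over all frames of all repeats, normalised to unit mass
#' (sum of density * cell area = 1). The log transform belongs to rendering
#' only; `log_floor` (default 1 / (10 * total frames)) records the smallest
#' display density.
#'
#' @param pool data.frame from [pose_ensemble()] (columns distance, rzz, and
#'   optionally traj, frame).
#' @param distance_bin Distance bin width (nm), default 0.1.
#' @param rzz_bin Rzz bin width, default 0.05.
#' @return Object of class `density_map`: `distance_edges`, `rzz_edges`,
#'   `counts`, `density`, `log_floor`, and the pooled points.
#' @export
density_map <- function(pool, distance_bin = 0.1, rzz_bin = 0.05) {
  if (!nrow(pool)) stop("empty ensemble pool")
  d <- pool$distance
  r <- pool$rzz
  d_edges <- seq(floor(min(d) / distance_bin) * distance_bin,
                 max(d) + distance_bin, by = distance_bin)
  r_edges <- seq(-1, 1 + 1e-12, by = rzz_bin)
  id <- findInterval(d, d_edges, rightmost.closed = TRUE)
  ir <- findInterval(pmin(r, 1 - 1e-12), r_edges)
  counts <- matrix(0, length(d_edges) - 1, length(r_edges) - 1)
  for (k in seq_along(id)) counts[id[k], ir[k]] <- counts[id[k], ir[k]] + 1
  n <- length(d)
  cell_area <- distance_bin * rzz_bin
  structure(
    list(distance_edges = d_edges, rzz_edges = r_edges, counts = counts,
         density = counts / (n * cell_area), n_total = n,
         log_floor = 1 / (10 * n), points = pool),
    class = "density_map"
  )
}

#' Detect binding modes as local maxima of the density map
#'
#' Cells with bin-centre distance below `distance_bound` and occupancy (cell
#' mass) at least `min_occupancy` that are 8-neighbourhood local maxima
#' become mode centres. All pooled frames below `distance_bound` are assigned
#' to the nearest centre (coordinates scaled by the bin widths); each mode's
#' occupancy is its share of all pooled frames, and its representative frame
#' is the pooled frame closest to the centre.
#'
#' @param map A `density_map`.
#' @param distance_bound Only cells closer than this are considered (nm).
#' @param min_occupancy Minimum cell mass (fraction of all frames),
#'   default 0.02.
#' @return List of `binding_mode` objects (possibly empty): each has
#'   `center` (distance, rzz), `occupancy`, `representative_frame`
#'   (traj, frame), and scoring `flags`.
#' @export
detect_modes <- function(map, distance_bound = 2.5, min_occupancy = 0.02) {
  cnt <- map$counts
  mass <- cnt / map$n_total
  d_mid <- (map$distance_edges[-1] + map$distance_edges[-length(map$distance_edges)]) / 2
  r_mid <- (map$rzz_edges[-1] + map$rzz_edges[-length(map$rzz_edges)]) / 2
  nd <- length(d_mid)
  nr <- length(r_mid)
  centers <- NULL
  for (i in seq_len(nd)) {
    if (d_mid[i] >= distance_bound) next
    for (j in seq_len(nr)) {
      if (mass[i, j] < min_occupancy) next
      ni <- max(1, i - 1):min(nd, i + 1)
      nj <- max(1, j - 1):min(nr, j + 1)
      if (cnt[i, j] == max(cnt[ni, nj]) &&
          sum(cnt[ni, nj] == cnt[i, j]) == 1) {
        centers <- rbind(centers, c(d_mid[i], r_mid[j]))
      }
    }
  }
  if (is.null(centers)) return(list())
  pts <- map$points[map$points$distance < distance_bound, , drop = FALSE]
  db <- map$distance_edges[2] - map$distance_edges[1]
  rb <- map$rzz_edges[2] - map$rzz_edges[1]
  d2 <- outer(pts$distance / db, centers[, 1] / db, "-")^2 +
    outer(pts$rzz / rb, centers[, 2] / rb, "-")^2
  assign <- max.col(-d2)
  lapply(seq_len(nrow(centers)), function(k) {
    members <- which(assign == k)
    rep_idx <- members[which.min(d2[members, k])]
    structure(
      list(
        center = c(distance = centers[k, 1], rzz = centers[k, 2]),
        occupancy = length(members) / map$n_total,
        representative_frame = list(traj = pts$traj[rep_idx],
                                    frame = pts$frame[rep_idx]),
        flags = list(probable = NA, physical = NA, productive = NA)
      ),
      class = "binding_mode"
    )
  })
}

#' Recompute Rzz of an ensemble against a selected binding mode
#'
#' The representative frame of the mode becomes the new reference structure
#' (so that frame maps to Rzz = 1 by construction); all Rzz values of the
#' ensemble are recomputed against it. The same reference should then be
#' reused for sister ensembles on other membrane compositions.
#'
#' @param trajs List of `membind_trajectory`.
#' @param mode A `binding_mode` (its representative frame indexes `trajs`).
#' @return List of `orientation_series`.
#' @export
rereference <- function(trajs, mode) {
  rf <- mode$representative_frame
  ref <- frame_bead_coords(trajs[[rf$traj]], rf$frame)
  lapply(trajs, rzz_series, reference = ref,
         reference_id = sprintf("mode(traj=%d,frame=%d)", rf$traj, rf$frame))
}

#' Score binding modes as probable / physically reasonable / productive
#'
#' A mode is probable when its occupancy reaches `probable_threshold`.
#' The physical and productive flags are geometric predicates on bead height
#' above the bilayer plane, evaluated on the mode's representative frame:
#' each mask is a list of constraints `list(labels =, min_z =, max_z =)`
#' (either bound optional, nm). Typical use: physical = termini must NOT be
#' buried (min_z), productive = the catalytic/binding face must touch the
#' membrane (max_z). Empty masks evaluate to TRUE.
#'
#' @param modes List of `binding_mode` from [detect_modes()].
#' @param trajs The ensemble the modes were detected in.
#' @param physical_mask,productive_mask Lists of constraints (see above).
#' @param probable_threshold Occupancy threshold, default 0.02.
#' @return The modes with `flags` filled in.
#' @export
score_modes <- function(modes, trajs, physical_mask = list(),
                        productive_mask = list(), probable_threshold = 0.02) {
  lapply(modes, function(m) {
    rf <- m$representative_frame
    tr <- trajs[[rf$traj]]
    xyz <- frame_bead_coords(tr, rf$frame)
    z <- xyz[, 3] - tr$bilayer$plane_z
    labels <- tr$body$bead_labels
    eval_mask <- function(mask) {
      for (con in mask) {
        unknown <- setdiff(con$labels, labels)
        if (length(unknown)) {
          stop("unknown bead label in mask: ", paste(unknown, collapse = ", "))
        }
        zi <- z[labels %in% con$labels]
        if (!is.null(con$min_z) && any(zi < con$min_z)) return(FALSE)
        if (!is.null(con$max_z) && !all(zi <= con$max_z)) return(FALSE)
      }
      TRUE
    }
    m$flags <- list(
      probable = m$occupancy >= probable_threshold,
      physical = eval_mask(physical_mask),
      productive = eval_mask(productive_mask)
    )
    m
  })
}

#' Classify a refinement trajectory: retained / rotated / unbound
#'
#' Relative to the first frame, computes the maximum change in COM height and
#' the maximum geodesic rotation angle acos((tr(R_rel) - 1) / 2). The label
#' is "unbound" if the minimum protein-lipid distance exceeds
#' `unbind_cutoff` for at least `dwell` consecutive frames, else "rotated" if
#' the maximum angle exceeds `angle_threshold`, else "retained".
#'
#' @param traj A `membind_trajectory` with >= 2 frames.
#' @param angle_threshold Degrees, default 45.
#' @param unbind_cutoff nm, default 1.5.
#' @param dwell Consecutive frames beyond the cutoff, default 5.
#' @return List: `label`, `max_delta_distance` (nm), `max_delta_angle` (deg).
#' @export
classify_refinement <- function(traj, angle_threshold = 45,
                                unbind_cutoff = 1.5, dwell = 5L) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  dz <- abs(traj$com[, 3] - traj$com[1, 3])
  r0 <- frame_rotation(traj, 1)
  ang <- vapply(seq_len(nf), function(i) {
    rrel <- frame_rotation(traj, i) %*% t(r0)
    acos(pmin(1, pmax(-1, (sum(diag(rrel)) - 1) / 2))) * 180 / pi
  }, numeric(1))
  mind <- min_distance_series(traj)$values
  runs <- rle(mind > unbind_cutoff)
  unbound <- any(runs$values & runs$lengths >= dwell)
  label <- if (unbound) "unbound" else if (max(ang) > angle_threshold) {
    "rotated"
  } else {
    "retained"
  }
  list(label = label, max_delta_distance = max(dz), max_delta_angle = max(ang))
}
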