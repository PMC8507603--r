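# Encounter/binding kinetics: minimum protein-lipid distance traces,
# hysteresis event segmentation, ensemble averaging, exponential decay fits.

#' Distance series object
#'
#' @param times Frame times (ps).
#' @param values Distances (nm).
#' @param kind "min-bead-pair" (minimum bead-lipid distance; for mean-field
#'   bilayers the minimum bead-plane distance) or "com-z".
#' @return Object of class `distance_series`.
#' @export
distance_series <- function(times, values, kind = "min-bead-pair") {
  stopifnot(length(times) == length(values))
  if (kind == "min-bead-pair" && any(values < -1e-9, na.rm = TRUE)) {
    stop("min-bead-pair distances must be non-negative")
  }
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 kind = kind),
            class = "distance_series")
}

#' Minimum protein-lipid distance per frame
#'
#' For explicit bilayers: the minimum over all bead-lipid pairs of the 3D
#' distance, using the xy minimum-image convention and the lipid z at the
#' bilayer plane. For mean-field bilayers the membrane is a continuum and the
#' minimum bead-plane distance is returned. A distance below 0.5 nm is the
#' conventional protein-bilayer contact criterion.
#'
#' @param traj A `membind_trajectory`.
#' @return A `distance_series` of kind "min-bead-pair".
#' @export
min_distance_series <- function(traj) {
  nf <- n_frames(traj)
  if (nf < 1) stop("trajectory has no frames")
  bil <- traj$bilayer
  vals <- numeric(nf)
  if (bil$mode == "explicit") {
    if (is.null(traj$lipid_xy) && is.null(bil$lipid_xy)) {
      stop("explicit trajectory has no lipid positions")
    }
    if (!is.null(bil$lipid_xy) && nrow(bil$lipid_xy) == 0) {
      stop("empty lipid set")
    }
    for (i in seq_len(nf)) {
      xyz <- frame_bead_coords(traj, i)
      lip <- frame_lipid_xy(traj, i)
      vals[i] <- min_pair_distance(xyz, lip, bil$box_xy, bil$plane_z)
    }
  } else {
    for (i in seq_len(nf)) {
      xyz <- frame_bead_coords(traj, i)
      vals[i] <- min(xyz[, 3]) - bil$plane_z
    }
  }
  distance_series(traj$times, pmax(vals, 0), kind = "min-bead-pair")
}

# Lipid xy positions at frame i (static bilayer positions if not recorded).
frame_lipid_xy <- function(traj, i) {
  if (!is.null(traj$lipid_xy)) {
    matrix(traj$lipid_xy[i, , ], ncol = 2)
  } else {
    traj$bilayer$lipid_xy
  }
}

min_pair_distance <- function(bead_xyz, lipid_xy, box_xy, plane_z) {
  best <- Inf
  for (i in seq_len(nrow(bead_xyz))) {
    dx <- min_image(lipid_xy[, 1] - bead_xyz[i, 1], box_xy[1])
    dy <- min_image(lipid_xy[, 2] - bead_xyz[i, 2], box_xy[2])
    dz <- plane_z - bead_xyz[i, 3]
    best <- min(best, min(dx * dx + dy * dy + dz * dz))
  }
  sqrt(best)
}

#' Segment a distance trace into bound/unbound events (hysteresis)
#'
#' A bound event starts when the distance drops below `on_cutoff` (default
#' 0.5 nm, the contact criterion) and ends only when the distance has
#' exceeded `off_cutoff` for at least `min_dwell` consecutive frames; the
#' event is then terminated at the first frame of that excursion. The
#' hysteresis suppresses frame-level chatter around the contact threshold.
#' With `off_cutoff == on_cutoff` and `min_dwell == 1` this reduces to simple
#' thresholding.
#'
#' @param series A `distance_series`.
#' @param on_cutoff Binding threshold (nm), default 0.5.
#' @param off_cutoff Unbinding threshold (nm), default 1.0;
#'   must be >= on_cutoff.
#' @param min_dwell Frames above `off_cutoff` required to end an event.
#' @return List of class `event_segmentation`: `bound_intervals` (two-column
#'   matrix of on/off times), `bound_index_intervals`, `fraction_bound`,
#'   `n_events`, `first_contact_time` (NA if never bound).
#' @export
segment_events <- function(series, on_cutoff = 0.5, off_cutoff = 1.0,
                           min_dwell = 5L) {
  if (off_cutoff < on_cutoff) stop("off_cutoff must be >= on_cutoff")
  v <- series$values
  n <- length(v)
  state <- FALSE
  above <- 0L
  start <- NA_integer_
  intervals <- NULL
  for (i in seq_len(n)) {
    if (!state) {
      if (v[i] < on_cutoff) {
        state <- TRUE
        start <- i
        above <- 0L
      }
    } else {
      if (v[i] > off_cutoff) {
        above <- above + 1L
        if (above >= min_dwell) {
          # event ends at the last frame before this excursion started
          intervals <- rbind(intervals, c(start, i - above))
          state <- FALSE
          above <- 0L
        }
      } else {
        above <- 0L
      }
    }
  }
  if (state) {
    # trajectory ends while bound (trailing sub-dwell excursion trimmed)
    intervals <- rbind(intervals, c(start, n - above))
  }
  frac <- if (is.null(intervals)) 0 else {
    sum(intervals[, 2] - intervals[, 1] + 1) / n
  }
  structure(
    list(
      bound_intervals = if (is.null(intervals)) {
        matrix(numeric(0), 0, 2)
      } else {
        cbind(series$times[intervals[, 1]], series$times[intervals[, 2]])
      },
      bound_index_intervals = if (is.null(intervals)) {
        matrix(integer(0), 0, 2)
      } else {
        intervals
      },
      fraction_bound = frac,
      n_events = if (is.null(intervals)) 0L else nrow(intervals),
      first_contact_time = if (is.null(intervals)) NA_real_ else
        series$times[intervals[1, 1]]
    ),
    class = "event_segmentation"
  )
}

#' Pointwise ensemble mean of distance traces
#'
#' Traces on different time grids are linearly interpolated onto the first
#' trace's grid (restricted to the overlapping range) before averaging.
#'
#' @param series_list Non-empty list of `distance_series`.
#' @return A `distance_series` of the pointwise mean.
#' @export
ensemble_mean_distance <- function(series_list) {
  if (!length(series_list)) stop("empty series list")
  t0 <- series_list[[1]]$times
  lo <- max(vapply(series_list, function(s) min(s$times), numeric(1)))
  hi <- min(vapply(series_list, function(s) max(s$times), numeric(1)))
  tt <- t0[t0 >= lo & t0 <= hi]
  vals <- vapply(series_list, function(s) {
    if (identical(s$times, tt)) s$values else
      stats::approx(s$times, s$values, xout = tt)$y
  }, numeric(length(tt)))
  distance_series(tt, rowMeans(as.matrix(vals)), kind = series_list[[1]]$kind)
}

#' Fit an exponential decay to an averaged distance trace
#'
#' Least-squares fit of d(t) = d_inf + (d0 - d_inf) exp(-t / tau). For fixed
#' tau the amplitudes are profiled out by linear least squares, and tau is
#' found by 1D optimisation of the profile RSS on a log scale; this makes the
#' fit robust without starting-value tuning. Initialisation/bounds follow
#' d0 = first value, d_inf = last value, tau in [span/1000, 100 * span].
#'
#' @param series A `distance_series` with at least 4 points.
#' @return List of class `decay_fit`: `d0`, `d_inf`, `tau` (ps), `rss`,
#'   `converged`. A constant series yields `converged = FALSE` with
#'   `d_inf = d0` (tau unidentifiable).
#' @export
fit_exponential_decay <- function(series) {
  tt <- series$times
  v <- series$values
  if (length(v) < 4) stop("need at least 4 points")
  if (any(!is.finite(tt)) || any(!is.finite(v))) {
    stop("non-finite values in series")
  }
  t0 <- tt - tt[1]
  span <- max(t0)
  if (stats::sd(v) < 1e-14) {
    return(structure(
      list(d0 = v[1], d_inf = v[1], tau = NA_real_, rss = 0,
           converged = FALSE),
      class = "decay_fit"
    ))
  }
  profile_rss <- function(log_tau) {
    basis <- exp(-t0 / exp(log_tau))
    fit <- stats::lm.fit(cbind(1, basis), v)
    sum(fit$residuals^2)
  }
  opt <- stats::optimize(profile_rss, interval = log(c(span / 1000, span * 100)),
                         tol = 1e-12)
  tau <- exp(opt$minimum)
  basis <- exp(-t0 / tau)
  fit <- stats::lm.fit(cbind(1, basis), v)
  d_inf <- fit$coefficients[1]
  d0 <- d_inf + fit$coefficients[2]
  # tau pinned at the search boundary means the decay is unidentifiable
  at_bound <- opt$minimum < log(span / 1000) + 1e-6 ||
    opt$minimum > log(span * 100) - 1e-6
  structure(
    list(d0 = unname(d0), d_inf = unname(d_inf), tau = tau,
         rss = sum(fit$residuals^2), converged = !at_bound),
    class = "decay_fit"
  )
}
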