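# Lipid contact and clustering statistics: per-group contact frequencies,
# basic-bead / phosphate contact counts, bound-PIP2 counting and radial
# enrichment of lipid species around the bound body.

# Pairwise bead-lipid 3D distances for one frame: n_beads x n_lipids.
frame_pair_distances <- function(traj, i, lipid_idx = NULL) {
  bil <- traj$bilayer
  xyz <- frame_bead_coords(traj, i)
  lip <- frame_lipid_xy(traj, i)
  if (!is.null(lipid_idx)) lip <- lip[lipid_idx, , drop = FALSE]
  n <- nrow(xyz)
  m <- nrow(lip)
  out <- matrix(0, n, m)
  for (b in seq_len(n)) {
    dx <- min_image(lip[, 1] - xyz[b, 1], bil$box_xy[1])
    dy <- min_image(lip[, 2] - xyz[b, 2], bil$box_xy[2])
    dz <- bil$plane_z - xyz[b, 3]
    out[b, ] <- sqrt(dx * dx + dy * dy + dz * dz)
  }
  out
}

#' Per-group, per-species contact frequency
#'
#' Fraction of frames in which any bead of a group lies within `cutoff`
#' (3D, xy minimum image) of any lipid of a species.
#'
#' @param traj Explicit-bilayer `membind_trajectory`.
#' @param groups Named list of bead index vectors, or NULL to group beads by
#'   their labels.
#' @param species Character vector of lipid species (default: all present).
#' @param cutoff Contact cutoff (nm), default 0.5.
#' @return Object of class `contact_profile`: `frequency` (groups x
#'   species matrix in [0, 1]), `cutoff`, `n_frames_used`.
#' @export
contact_frequency <- function(traj, groups = NULL, species = NULL,
                              cutoff = 0.5) {
  bil <- traj$bilayer
  if (bil$mode != "explicit") stop("contact analysis needs explicit lipids")
  if (is.null(groups)) {
    labs <- traj$body$bead_labels
    groups <- split(seq_along(labs), labs)
  }
  present <- unique(bil$lipid_species)
  if (is.null(species)) species <- present
  unknown <- setdiff(species, present)
  if (length(unknown)) {
    stop("unknown species: ", paste(unknown, collapse = ", "))
  }
  nf <- n_frames(traj)
  hits <- matrix(0, length(groups), length(species),
                 dimnames = list(names(groups), species))
  for (i in seq_len(nf)) {
    d <- frame_pair_distances(traj, i)
    for (s in seq_along(species)) {
      cols <- bil$lipid_species == species[s]
      dmin_bead <- apply(d[, cols, drop = FALSE], 1, min)
      for (g in seq_along(groups)) {
        if (min(dmin_bead[groups[[g]]]) < cutoff) {
          hits[g, s] <- hits[g, s] + 1
        }
      }
    }
  }
  structure(
    list(frequency = hits / nf, cutoff = cutoff, n_frames_used = nf,
         groups = groups),
    class = "contact_profile"
  )
}

#' Basic-bead / phosphate contact counts per frame
#'
#' Counts (basic bead, anionic head group) pairs within `cutoff` per frame;
#' in the toy model the "phosphate" is the charged head bead of PS/PIP2
#' (default species PIP2). Mean counts across systems correlate with PMF
#' well depths; [contact_depth_correlation()] computes that correlation.
#'
#' @param traj Explicit-bilayer trajectory whose body has beads labelled
#'   "basic".
#' @param cutoff Contact cutoff (nm), default 0.5.
#' @param species Lipid species counted, default "PIP2".
#' @return List: `counts` (per frame), `mean`, `times`.
#' @export
basic_phosphate_contacts <- function(traj, cutoff = 0.5, species = "PIP2") {
  basic <- which(traj$body$bead_labels == "basic")
  if (!length(basic)) stop("body has no beads labelled 'basic'")
  cols <- which(traj$bilayer$lipid_species %in% species)
  nf <- n_frames(traj)
  counts <- integer(nf)
  for (i in seq_len(nf)) {
    d <- frame_pair_distances(traj, i, lipid_idx = cols)
    counts[i] <- sum(d[basic, , drop = FALSE] < cutoff)
  }
  list(counts = counts, mean = mean(counts), times = traj$times)
}

#' Correlation between mean contact counts and PMF well depths
#'
#' @param mean_counts Mean basic-phosphate contact counts across systems.
#' @param well_depths Matching PMF well depths (kJ/mol).
#' @return Pearson correlation coefficient.
#' @export
contact_depth_correlation <- function(mean_counts, well_depths) {
  stopifnot(length(mean_counts) == length(well_depths))
  stats::cor(mean_counts, well_depths)
}

#' Radial enrichment of a lipid species around the bound body
#'
#' Over bound frames, histograms the species' head groups in annuli around
#' the body-COM xy footprint (minimum image) and divides by the surface
#' density expected from the leaflet composition. Enrichment ~1 everywhere
#' means no clustering; a first-annulus enrichment well above 1 with the
#' bound count saturating at the leaflet's PIP2 content is the clustering
#' signature of polyanionic lipids under a bound polybasic face.
#'
#' @param traj Explicit-bilayer trajectory.
#' @param r_max Largest annulus radius (nm), must be <= half the box edge.
#' @param n_bins Number of annuli.
#' @param species Species analysed, default "PIP2".
#' @param bound_frames Frame indices to use; default: bound frames from
#'   [segment_events()] on the minimum-distance trace (all frames if the
#'   segmentation finds none and `require_bound = FALSE`).
#' @param bound_cutoff Bead-lipid distance defining a bound lipid for
#'   `mean_bound_count` (nm), default 1.5 (head-to-bead contact sphere of
#'   the toy geometry).
#' @param require_bound Error if no bound frames exist (default TRUE).
#' @return Object of class `enrichment_profile`: `radial_bin_edges`,
#'   `enrichment`, `mean_bound_count`, `n_frames_used`, `expected_density`.
#' @export
pip2_enrichment <- function(traj, r_max = 3, n_bins = 6, species = "PIP2",
                            bound_frames = NULL, bound_cutoff = 1.5,
                            require_bound = TRUE) {
  bil <- traj$bilayer
  if (bil$mode != "explicit") stop("enrichment needs explicit lipids")
  if (r_max > min(bil$box_xy) / 2 + 1e-9) {
    stop("r_max must not exceed half the box edge")
  }
  if (is.null(bound_frames)) {
    seg <- segment_events(min_distance_series(traj))
    idx <- seg$bound_index_intervals
    bound_frames <- if (nrow(idx)) {
      unlist(lapply(seq_len(nrow(idx)), function(k) idx[k, 1]:idx[k, 2]))
    } else {
      integer(0)
    }
  }
  if (!length(bound_frames)) {
    if (require_bound) stop("no bound frames in trajectory")
    bound_frames <- seq_len(n_frames(traj))
  }
  cols <- which(bil$lipid_species == species)
  if (!length(cols)) stop("species absent from bilayer: ", species)
  edges <- seq(0, r_max, length.out = n_bins + 1)
  areas <- pi * diff(edges^2)
  counts <- numeric(n_bins)
  bound_counts <- numeric(length(bound_frames))
  for (k in seq_along(bound_frames)) {
    i <- bound_frames[k]
    lip <- frame_lipid_xy(traj, i)[cols, , drop = FALSE]
    dx <- min_image(lip[, 1] - traj$com[i, 1], bil$box_xy[1])
    dy <- min_image(lip[, 2] - traj$com[i, 2], bil$box_xy[2])
    r <- sqrt(dx * dx + dy * dy)
    counts <- counts + tabulate(findInterval(r, edges,
                                             rightmost.closed = TRUE),
                                nbins = n_bins)
    d <- frame_pair_distances(traj, i, lipid_idx = cols)
    bound_counts[k] <- sum(apply(d, 2, min) < bound_cutoff)
  }
  expected <- length(cols) / prod(bil$box_xy) # lipids per nm^2
  obs_density <- counts / (length(bound_frames) * areas)
  structure(
    list(radial_bin_edges = edges, enrichment = obs_density / expected,
         mean_bound_count = mean(bound_counts),
         n_frames_used = length(bound_frames),
         expected_density = expected, annulus_areas = areas),
    class = "enrichment_profile"
  )
}

#' First-annulus enrichment per species
#'
#' Direct PIP2-vs-PS-vs-PC clustering contrast: the enrichment of each
#' species in the innermost annulus around the bound body.
#'
#' @param traj Explicit-bilayer trajectory.
#' @param r_first Radius of the first annulus (nm), default 1.5.
#' @param ... Passed to [pip2_enrichment()] (e.g. `bound_frames`).
#' @return Named numeric vector of first-annulus enrichments.
#' @export
species_clustering_contrast <- function(traj, r_first = 1.5, ...) {
  species <- names(traj$bilayer$species_counts)[
    traj$bilayer$species_counts > 0]
  vapply(species, function(s) {
    pip2_enrichment(traj, r_max = 2 * r_first, n_bins = 2, species = s,
                    ...)$enrichment[1]
  }, numeric(1))
}
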