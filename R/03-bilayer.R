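# Planar bilayer model: explicit 2D head-group positions for the upper
# (protein-facing) leaflet, or a mean-field uniformly charged plane.

DEFAULT_SPECIES_CHARGES <- c(PC = 0, PS = -1, PIP2 = -5)

#' Build a planar bilayer with a given lipid composition
#'
#' Integer per-leaflet lipid counts are allocated from the target molar
#' fractions by the largest-remainder rule, and upper-leaflet head groups are
#' placed uniformly at random in the periodic box. The canonical compositions
#' are PC (100:0:0), PC:PS (80:20) and PC:PS:PIP2 (80:15:5); at 80 lipids per
#' leaflet the latter yields 4 PIP2 per leaflet (8 per bilayer).
#'
#' In mean-field mode no explicit positions are stored; the leaflet is
#' summarised by its surface charge density (e/nm^2).
#'
#' @param n_lipids_per_leaflet Number of lipids in one leaflet.
#' @param fractions Named molar fractions (must sum to 1), e.g.
#'   `c(PC = 0.8, PS = 0.15, PIP2 = 0.05)`.
#' @param box_xy Periodic box edge lengths in nm (length 2 or scalar).
#' @param seed Optional integer seed for the random placement.
#' @param species_charges Named head-group charges in e; defaults
#'   PC 0, PS -1, PIP2 -5.
#' @param plane_z Height of the bilayer surface plane (nm), default 0.
#' @param mode "explicit" (diffusing head groups) or "mean-field"
#'   (uniformly charged plane).
#' @return An object of class `bilayer_model`.
#' @export
build_bilayer <- function(n_lipids_per_leaflet,
                          fractions,
                          box_xy = c(7, 7),
                          seed = NULL,
                          species_charges = DEFAULT_SPECIES_CHARGES,
                          plane_z = 0,
                          mode = c("explicit", "mean-field")) {
  mode <- match.arg(mode)
  if (length(box_xy) == 1) box_xy <- rep(box_xy, 2)
  if (n_lipids_per_leaflet < 1) stop("invalid composition: need n >= 1 lipids")
  if (any(fractions < 0)) stop("invalid composition: negative fraction")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("invalid composition: fractions must sum to 1")
  }
  if (is.null(names(fractions)) || any(!nzchar(names(fractions)))) {
    stop("fractions must be named by species")
  }
  missing_q <- setdiff(names(fractions), names(species_charges))
  if (length(missing_q)) {
    stop("no charge defined for species: ", paste(missing_q, collapse = ", "))
  }
  counts <- largest_remainder(n_lipids_per_leaflet, fractions)
  species <- rep(names(counts), counts)
  lipid_xy <- NULL
  if (mode == "explicit") {
    lipid_xy <- with_seed(seed, matrix(
      stats::runif(2 * n_lipids_per_leaflet) * rep(box_xy, each = n_lipids_per_leaflet),
      ncol = 2
    ))
  }
  charges <- species_charges[names(counts)]
  structure(
    list(
      box_xy = as.numeric(box_xy),
      species_counts = counts,
      species_charges = charges,
      lipid_species = species,
      lipid_xy = lipid_xy,
      plane_z = plane_z,
      mode = mode,
      seed = seed
    ),
    class = "bilayer_model"
  )
}

# Largest-remainder (Hamilton) apportionment of n items to named fractions.
largest_remainder <- function(n, fractions) {
  quota <- n * fractions
  counts <- floor(quota)
  short <- n - sum(counts)
  if (short > 0) {
    rem <- quota - counts
    # ties broken by listing order, which is deterministic
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

# Upper-leaflet surface charge density in e/nm^2.
surface_charge_density <- function(bilayer) {
  total_q <- sum(bilayer$species_counts * bilayer$species_charges)
  total_q / prod(bilayer$box_xy)
}

# Per-lipid head-group charges in leaflet order.
lipid_charges <- function(bilayer) {
  unname(bilayer$species_charges[bilayer$lipid_species])
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat(
    "bilayer_model (", x$mode, "): box ", x$box_xy[1], "x", x$box_xy[2],
    " nm; upper leaflet ",
    paste(sprintf("%s=%d", names(x$species_counts), x$species_counts),
          collapse = " "),
    "; sigma = ", signif(surface_charge_density(x), 3), " e/nm^2\n",
    sep = ""
  )
  invisible(x)
}
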