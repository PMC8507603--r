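# Rigid multi-bead protein body: the coarse stand-in for a peripheral
# membrane-binding domain (e.g. a C2 domain) with charged surface patches.

#' Construct a rigid bead-model protein body
#'
#' The body is a rigid collection of beads given in body-frame coordinates
#' (nm), each carrying an elementary charge and a residue-class label
#' (e.g. "basic", "core", "terminus"). The body frame is re-centred so the
#' centre of mass (uniform bead masses) sits at the origin. At least four
#' non-coplanar beads are required so that the orientation of the body is
#' well defined.
#'
#' @param bead_positions n x 3 matrix of body-frame coordinates (nm).
#' @param bead_charges Numeric vector of elementary charges per bead.
#' @param bead_labels Character vector of residue-class tags per bead.
#' @return An object of class `protein_body`.
#' @export
protein_body <- function(bead_positions, bead_charges, bead_labels) {
  bead_positions <- as.matrix(bead_positions)
  storage.mode(bead_positions) <- "double"
  n <- nrow(bead_positions)
  if (ncol(bead_positions) != 3) stop("bead_positions must be n x 3")
  if (n < 4) stop("need at least 4 beads for a well-defined orientation")
  if (length(bead_charges) != n) stop("bead_charges length mismatch")
  if (length(bead_labels) != n) stop("bead_labels must cover all beads")
  centred <- sweep(bead_positions, 2, colMeans(bead_positions))
  # Non-coplanarity: the centred coordinates must span all three dimensions.
  sv <- svd(centred)$d
  if (sv[3] < 1e-9 * sv[1]) {
    stop("beads are coplanar; orientation would be ill-defined")
  }
  structure(
    list(
      bead_positions = centred,
      bead_charges = as.numeric(bead_charges),
      bead_labels = as.character(bead_labels),
      reference_orientation = diag(3)
    ),
    class = "protein_body"
  )
}

#' Built-in C2-like bead body preset
#'
#' A nine-bead rigid body shaped like a small beta-sandwich domain: three
#' basic (+1 e) beads form a membrane-binding loop face at the bottom
#' (body-frame z = -0.7 nm), four neutral core beads sit mid-height, and two
#' acidic (-1 e) terminus beads cap the opposite face. With the identity
#' orientation the basic face points towards the bilayer, which is the
#' productive binding mode of the toy model.
#'
#' @param basic_charge Charge per basic loop bead (default +1 e).
#' @return A `protein_body`.
#' @export
c2_body <- function(basic_charge = 1) {
  pos <- rbind(
    c(0.50, 0.00, -0.70),
    c(-0.25, 0.433, -0.70),
    c(-0.25, -0.433, -0.70),
    c(0.55, 0.55, 0.10),
    c(-0.55, 0.55, 0.10),
    c(-0.55, -0.55, 0.10),
    c(0.55, -0.55, 0.10),
    c(0.30, 0.00, 0.90),
    c(-0.30, 0.00, 0.90)
  )
  protein_body(
    bead_positions = pos,
    bead_charges = c(rep(basic_charge, 3), rep(0, 4), rep(-1, 2)),
    bead_labels = c(rep("basic", 3), rep("core", 4), rep("terminus", 2))
  )
}

#' @export
print.protein_body <- function(x, ...) {
  cat(
    "protein_body:", nrow(x$bead_positions), "beads, net charge",
    sum(x$bead_charges), "e; labels:",
    paste(unique(x$bead_labels), collapse = ", "), "\n"
  )
  invisible(x)
}

# Lab-frame bead coordinates for a pose (rotation matrix R, COM com).
body_lab_coords <- function(body, R, com) {
  sweep(body$bead_positions %*% t(R), 2, com, "+")
}
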