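# On-disk trajectory container: a directory of plain-text files
#   meta.json   composition, charges, params subset, seed, metadata
#   frames.csv  time, com_x, com_y, com_z, q_w, q_x, q_y, q_z
#   lipids.csv  frame, lipid, x, y        (explicit bilayers only)
# Values are written with 17 significant digits so that a read/write
# round-trip is lossless to well below 1e-12.

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a trajectory to a plain-text container directory
#'
#' @param traj A `membind_trajectory`.
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  bil <- traj$bilayer
  meta <- list(
    format = "membind-trajectory-v1",
    n_frames = n_frames(traj),
    frame_interval = traj$frame_interval,
    bilayer = list(
      mode = bil$mode,
      box_xy = bil$box_xy,
      plane_z = bil$plane_z,
      species_counts = as.list(bil$species_counts),
      species_charges = as.list(bil$species_charges),
      lipid_species = bil$lipid_species
    ),
    body = list(
      bead_positions = traj$body$bead_positions,
      bead_charges = traj$body$bead_charges,
      bead_labels = traj$body$bead_labels
    ),
    metadata = traj$metadata
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  fr <- data.frame(
    time = fmt17(traj$times),
    com_x = fmt17(traj$com[, 1]), com_y = fmt17(traj$com[, 2]),
    com_z = fmt17(traj$com[, 3]),
    q_w = fmt17(traj$quat[, 1]), q_x = fmt17(traj$quat[, 2]),
    q_y = fmt17(traj$quat[, 3]), q_z = fmt17(traj$quat[, 4])
  )
  utils::write.csv(fr, file.path(path, "frames.csv"), row.names = FALSE,
                   quote = FALSE)
  if (!is.null(traj$lipid_xy)) {
    d <- dim(traj$lipid_xy)
    li <- data.frame(
      frame = rep(seq_len(d[1]), times = d[2]),
      lipid = rep(seq_len(d[2]), each = d[1]),
      x = fmt17(as.vector(traj$lipid_xy[, , 1])),
      y = fmt17(as.vector(traj$lipid_xy[, , 2]))
    )
    utils::write.csv(li, file.path(path, "lipids.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory from a container directory
#'
#' @param path Directory written by [write_trajectory()].
#' @return A `membind_trajectory`.
#' @export
read_trajectory <- function(path) {
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(meta_file)) {
    stop("not a trajectory container (missing meta.json): ", path)
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (!identical(meta$format, "membind-trajectory-v1")) {
    stop("unrecognized container format in ", meta_file)
  }
  fr <- utils::read.csv(file.path(path, "frames.csv"),
                        colClasses = "numeric")
  if (nrow(fr) != meta$n_frames) {
    stop("truncated container: expected ", meta$n_frames, " frames, found ",
         nrow(fr))
  }
  bp <- meta$body$bead_positions
  if (is.list(bp)) bp <- do.call(rbind, bp)
  bead_pos <- matrix(as.numeric(bp), ncol = 3)
  body <- protein_body(bead_pos, meta$body$bead_charges,
                       meta$body$bead_labels)
  lipid_xy <- NULL
  counts <- unlist(meta$bilayer$species_counts)
  charges <- unlist(meta$bilayer$species_charges)
  if (meta$bilayer$mode == "explicit") {
    li <- utils::read.csv(file.path(path, "lipids.csv"),
                          colClasses = "numeric")
    nl <- max(li$lipid)
    lipid_xy <- array(0, c(meta$n_frames, nl, 2))
    lipid_xy[, , 1] <- matrix(li$x, meta$n_frames, nl)
    lipid_xy[, , 2] <- matrix(li$y, meta$n_frames, nl)
  }
  bil <- structure(
    list(
      box_xy = meta$bilayer$box_xy,
      species_counts = stats::setNames(as.integer(counts), names(counts)),
      species_charges = charges,
      lipid_species = meta$bilayer$lipid_species,
      lipid_xy = if (is.null(lipid_xy)) NULL else
        lipid_xy[meta$n_frames, , , drop = TRUE],
      plane_z = meta$bilayer$plane_z,
      mode = meta$bilayer$mode,
      seed = meta$metadata$seed
    ),
    class = "bilayer_model"
  )
  trajectory(
    times = fr$time,
    com = as.matrix(fr[, c("com_x", "com_y", "com_z")]),
    quat = as.matrix(fr[, c("q_w", "q_x", "q_y", "q_z")]),
    body = body, bilayer = bil, lipid_xy = lipid_xy,
    frame_interval = meta$frame_interval,
    metadata = if (is.null(meta$metadata)) list() else as.list(meta$metadata)
  )
}
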