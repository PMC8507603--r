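# Protocol orchestration: run the full analysis chain (ensemble encounter
# simulations -> kinetics -> orientation modes -> umbrella/WHAM -> FEP ->
# contacts -> consistency report) from one configuration, with per-stage
# seed management and a machine-readable JSON report.

#' Default protocol configuration
#'
#' Returns the full configuration list for [run_protocol()], with the
#' standard protocol constants (25 repeats, 4.4 nm initial separation,
#' 0.05 nm window spacing, k = 2000 kJ/mol/nm^2, 21 lambda states, 5 FEP
#' repeats, 323 K) but desk-scale ensemble sizes. Any field can be
#' overridden via `...` before validation.
#'
#' @param ... Named overrides merged over the defaults.
#' @return A named list (protocol configuration).
#' @export
default_protocol_config <- function(...) {
  cfg <- list(
    body = "c2",
    n_lipids_per_leaflet = 80,
    box_xy = c(7, 7),
    membranes = list(
      PC = c(PC = 1),
      `PC:PS` = c(PC = 0.8, PS = 0.2),
      `PC:PS:PIP2` = c(PC = 0.8, PS = 0.15, PIP2 = 0.05)
    ),
    n_repeats = 5,
    n_steps = 1500,
    record_every = 10,
    min_separation = 4.4,
    on_cutoff = 0.5,
    off_cutoff = 1.0,
    min_dwell = 5,
    umbrella = list(z_min = 0.9, z_max = 3.5, spacing = 0.05, k = 2000,
                    n_samples = 1500, n_equil = 150),
    fep = list(n_states = 21, n_samples = 250, n_repeats = 3),
    n_bootstrap = 20,
    seed = 1,
    sim = list()
  )
  utils::modifyList(cfg, list(...))
}

protocol_body <- function(cfg) {
  if (identical(cfg$body, "c2")) c2_body() else
    protein_body(cfg$body$bead_positions, cfg$body$bead_charges,
                 cfg$body$bead_labels)
}

# Stable 32-bit FNV-1a hash of the deparsed configuration (provenance).
# All arithmetic stays inside exact double precision.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    lo <- bitwXor(h %% 65536, b)
    hi <- h %/% 65536
    h <- (((hi * prime) %% 65536) * 65536 + lo * prime) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full membrane-binding analysis protocol
#'
#' Executes, in order: (A) replicated encounter simulations on each membrane
#' composition; (B) minimum-distance kinetics with event segmentation and an
#' exponential fit to the ensemble-averaged trace; (C) distance/orientation
#' density maps, mode detection, scoring and re-referencing to the primary
#' mode of the PIP2 membrane; (D) umbrella sampling + WHAM potentials of
#' mean force for the PIP2 membrane and its alchemical end state, with well
#' depths and their difference; (E) per-lipid PIP2 -> PC FEP on the bound
#' pose with the FEP-vs-dPMF consistency report; (F) contact/enrichment
#' statistics and a retained/rotated/unbound classification of a bound-pose
#' continuation run. Every stage writes its outputs under `out_dir` and the
#' report carries the configuration hash and all seeds.
#'
#' @param config Configuration list from [default_protocol_config()], or a
#'   path to a JSON file with the same fields.
#' @param out_dir Output directory.
#' @param quiet Suppress per-stage log lines.
#' @return The protocol report (also written to `out_dir/report.json`),
#'   invisibly.
#' @export
run_protocol <- function(config = default_protocol_config(),
                         out_dir = "membind-out", quiet = FALSE) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
    config$membranes <- lapply(config$membranes, unlist)
  }
  cfg <- utils::modifyList(default_protocol_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t_start <- proc.time()[["elapsed"]]
  body <- protocol_body(cfg)
  params <- do.call(sim_params, cfg$sim)
  report <- list(provenance = list(
    config_hash = config_hash(cfg), seed = cfg$seed,
    package_version = as.character(utils::packageVersion("membind"))
  ))

  # A/B: encounter ensembles + kinetics per membrane
  kinetics <- list()
  ensembles <- list()
  for (mi in seq_along(cfg$membranes)) {
    label <- names(cfg$membranes)[mi]
    bil <- build_bilayer(cfg$n_lipids_per_leaflet, cfg$membranes[[mi]],
                         cfg$box_xy, seed = cfg$seed + 1000 * mi,
                         mode = "mean-field")
    trajs <- simulate_ensemble(
      body, bil, params, n_repeats = cfg$n_repeats, n_steps = cfg$n_steps,
      record_every = cfg$record_every, min_separation = cfg$min_separation,
      seed_base = cfg$seed + 1000 * mi, membrane_label = label
    )
    ensembles[[label]] <- trajs
    series <- lapply(trajs, min_distance_series)
    segs <- lapply(series, segment_events, on_cutoff = cfg$on_cutoff,
                   off_cutoff = cfg$off_cutoff, min_dwell = cfg$min_dwell)
    mean_series <- ensemble_mean_distance(series)
    fit <- fit_exponential_decay(mean_series)
    kinetics[[label]] <- list(
      fraction_bound = mean(vapply(segs, `[[`, numeric(1), "fraction_bound")),
      n_events = sum(vapply(segs, `[[`, integer(1), "n_events")),
      decay = list(d0 = fit$d0, d_inf = fit$d_inf, tau = fit$tau,
                   converged = fit$converged)
    )
    utils::write.csv(
      data.frame(t = mean_series$times, distance = mean_series$values),
      file.path(out_dir, paste0("kinetics_", gsub("[^A-Za-z0-9]", "_", label),
                                ".csv")),
      row.names = FALSE
    )
    log_stage("stage kinetics [%s]: fraction_bound %.3f",
              label, kinetics[[label]]$fraction_bound)
  }
  report$kinetics <- kinetics
  write_trajectory(ensembles[[length(ensembles)]][[1]],
                   file.path(out_dir, "trajectory_rep1"))

  # C: orientation modes on the PIP2-membrane ensemble
  pip2_label <- names(cfg$membranes)[length(cfg$membranes)]
  trajs <- ensembles[[pip2_label]]
  ref <- reference_from_ensemble(trajs)
  pool <- pose_ensemble(trajs, ref)
  map <- density_map(pool)
  modes <- detect_modes(map, distance_bound = cfg$min_separation)
  modes <- score_modes(
    modes, trajs,
    physical_mask = list(list(labels = "terminus", min_z = 0.5)),
    productive_mask = list(list(labels = "basic", max_z = 1.5))
  )
  if (length(modes)) {
    occ <- vapply(modes, `[[`, numeric(1), "occupancy")
    primary <- modes[[which.max(occ)]]
    rereferenced <- rereference(trajs, primary)
    report$modes <- lapply(modes, function(m) {
      list(center = as.list(m$center), occupancy = m$occupancy,
           representative_frame = m$representative_frame, flags = m$flags)
    })
    bound_pose_traj <- trajs[[primary$representative_frame$traj]]
    bound_frame <- primary$representative_frame$frame
    bound_R <- frame_rotation(bound_pose_traj, bound_frame)
  } else {
    report$modes <- list()
    bound_R <- diag(3) # fall back to the productive basic-face-down pose
  }
  log_stage("stage modes: %d mode(s) detected", length(modes))

  # D: umbrella sampling + WHAM on PIP2 membrane and its FEP end state
  um <- cfg$umbrella
  centers <- seq(um$z_min, um$z_max, by = um$spacing)
  frac <- cfg$membranes[[pip2_label]]
  n_pip2 <- largest_remainder(cfg$n_lipids_per_leaflet, frac)[["PIP2"]]
  end_counts <- largest_remainder(cfg$n_lipids_per_leaflet, frac)
  end_counts["PC"] <- end_counts["PC"] + end_counts["PIP2"]
  end_counts["PIP2"] <- 0
  mk_bil <- function(counts, seed) {
    n <- sum(counts)
    build_bilayer(n, counts / n, cfg$box_xy, seed = seed)
  }
  bil_pip2 <- mk_bil(largest_remainder(cfg$n_lipids_per_leaflet, frac),
                     cfg$seed + 71)
  bil_end <- mk_bil(end_counts, cfg$seed + 72)
  depths <- list()
  profiles <- list()
  for (nm in c("pip2", "end_state")) {
    bil <- if (nm == "pip2") bil_pip2 else bil_end
    st <- system_state(body, bil, c(cfg$box_xy / 2, 2), bound_R)
    win <- generate_umbrella_windows(st, params, centers,
                                     force_constant = um$k,
                                     n_samples = um$n_samples,
                                     n_equil = um$n_equil,
                                     seed = cfg$seed + 80 + (nm == "pip2"))
    ws <- wham_settings(bin_width = um$spacing,
                        temperature = params$temperature,
                        n_bootstrap = cfg$n_bootstrap,
                        seed = cfg$seed + 90)
    prof <- bootstrap_pmf(win, ws, profile = wham(win, ws))
    profiles[[nm]] <- prof
    depths[[nm]] <- well_depth(prof)
    utils::write.csv(
      data.frame(z = prof$z, g = prof$g, g_err = prof$g_err,
                 n_eff = prof$n_eff),
      file.path(out_dir, paste0("pmf_", nm, ".csv")), row.names = FALSE
    )
    log_stage("stage wham [%s]: well depth %.2f +/- %.2f kJ/mol", nm,
              depths[[nm]]$depth, depths[[nm]]$depth_err)
  }
  dpmf <- delta_pmf(depths$pip2, depths$end_state)
  report$pmf <- list(
    depth_pip2 = depths$pip2$depth, depth_pip2_err = depths$pip2$depth_err,
    depth_end_state = depths$end_state$depth,
    depth_end_state_err = depths$end_state$depth_err,
    delta_pmf = dpmf$value, delta_pmf_err = dpmf$err
  )

  # E: per-lipid FEP on the bound pose + consistency report
  st_bound <- system_state(body, bil_pip2,
                           c(cfg$box_xy / 2, depths$pip2$z_min), bound_R)
  fep <- run_fep(st_bound, params, n_states = cfg$fep$n_states,
                 n_samples = cfg$fep$n_samples,
                 n_repeats = cfg$fep$n_repeats, seed = cfg$seed + 500)
  consistency <- fep_pmf_consistency(fep, dpmf)
  report$fep <- list(
    per_lipid_ddg = fep$per_lipid_ddg, per_lipid_err = fep$per_lipid_err,
    total = fep$total, total_err = fep$total_err,
    n_repeats = fep$n_repeats, estimator = fep$estimator,
    neutralizers_per_lipid = fep$neutralizers
  )
  report$consistency <- unclass(consistency)
  log_stage("stage fep: total %.2f +/- %.2f kJ/mol (dPMF %.2f); consistent: %s",
            fep$total, fep$total_err, dpmf$value, consistency$consistent)

  # F: contacts/enrichment on a bound-pose lipid relaxation + classification
  relax <- simulate_bd(st_bound, params, n_steps = 400, record_every = 4,
                       move_body = FALSE, seed = cfg$seed + 600,
                       metadata = list(stage = "bound_relaxation"))
  contacts <- contact_frequency(relax)
  enr <- pip2_enrichment(relax, r_max = min(cfg$box_xy) / 2 - 0.01,
                         require_bound = FALSE,
                         bound_frames = seq_len(n_frames(relax)))
  refine <- simulate_bd(
    system_state(body, relax$bilayer, st_bound$body_com, bound_R),
    params, n_steps = 400, record_every = 4, seed = cfg$seed + 601
  )
  cls <- classify_refinement(refine)
  report$contacts <- list(
    frequency = as.data.frame(contacts$frequency),
    pip2_first_annulus_enrichment = enr$enrichment[1],
    mean_bound_pip2 = enr$mean_bound_count,
    n_pip2_upper_leaflet = n_pip2
  )
  report$refinement <- cls
  log_stage("stage contacts: first-annulus PIP2 enrichment %.2f; refinement %s",
            enr$enrichment[1], cls$label)

  report$elapsed_s <- proc.time()[["elapsed"]] - t_start
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(report)
}

#' Read a trajectory through the format adapter
#'
#' Bridges externally produced trajectories into the analysis stages. Only
#' the native plain-text container is supported without optional
#' dependencies; standard MD formats would require a trajectory-reading
#' package and raise an actionable error when absent.
#'
#' @param path Container directory (native) or trajectory file.
#' @param format "native" or an MD format name.
#' @return A `membind_trajectory`.
#' @export
read_trajectory_adapter <- function(path, format = "native") {
  if (identical(format, "native")) {
    return(read_trajectory(path))
  }
  stop(sprintf(
    "reading '%s' trajectories requires an optional MD I/O dependency that is not installed; convert to the native container instead",
    format
  ))
}
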