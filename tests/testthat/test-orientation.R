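# Rotation matrices, the Rzz statistic, density maps, binding modes and
# refinement classification.

test_that("Kabsch rotation: identity, known rotation, degenerate input", {
  ref <- c2_body()$bead_positions
  expect_equal(rotation_matrix(ref, ref), diag(3), tolerance = 1e-9)
  R <- rotation_about(c(2, -1, 0.5), 1.1)
  expect_equal(rotation_matrix(ref, ref %*% t(R)), R, tolerance = 1e-9)
  line <- cbind(1:4, 0, 0)
  expect_error(rotation_matrix(line, line), "collinear")
  expect_error(rotation_matrix(ref[1:3, ], ref), "mismatch")
})

test_that("Kabsch beats random rotations on noisy data", {
  set.seed(6)
  ref <- c2_body()$bead_positions
  R <- rotation_about(c(1, 1, 1), 0.8)
  noisy <- ref %*% t(R) + matrix(stats::rnorm(length(ref), 0, 0.05),
                                 nrow(ref))
  rmsd <- function(Rot) sqrt(mean(rowSums((noisy - ref %*% t(Rot))^2)))
  best <- rmsd(rotation_matrix(ref, noisy))
  rand <- vapply(seq_len(10000), function(i)
    rmsd(quat_to_matrix(as.numeric(random_quaternion(1)))), numeric(1))
  expect_true(all(best <= rand + 1e-12))
})

test_that("Rzz endpoint identities hold", {
  body <- c2_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field")
  ref_pose <- list(com = c(3.5, 3.5, 2), R = diag(3))
  poses <- list(
    ref_pose,
    list(com = c(3.5, 3.5, 2), R = rotation_about("x", pi)),
    list(com = c(1, 1, 3), R = rotation_about("x", pi / 2))
  )
  tr <- pose_trajectory(body, bil, poses)
  rz <- rzz_series(tr, membind:::frame_bead_coords(tr, 1))
  expect_equal(rz$rzz[1], 1, tolerance = 1e-12)
  expect_equal(rz$rzz[2], -1, tolerance = 1e-12)
  expect_equal(rz$rzz[3], 0, tolerance = 1e-12)
})

test_that("Rzz is invariant to rotations about z", {
  body <- c2_body()
  ref <- body$bead_positions
  set.seed(8)
  for (i in 1:25) {
    R <- quat_to_matrix(as.numeric(random_quaternion(1)))
    pre <- rotation_about("z", stats::runif(1, 0, 2 * pi))
    post <- rotation_about("z", stats::runif(1, 0, 2 * pi))
    r1 <- rotation_matrix(ref, ref %*% t(R))[3, 3]
    r2 <- rotation_matrix(ref, ref %*% t(post %*% R %*% pre))[3, 3]
    expect_lt(abs(r1 - r2), 1e-9)
  }
})

test_that("COM height series and its direct recomputation agree", {
  body <- c2_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field", plane_z = 0)
  poses <- lapply(seq(4, 1, length.out = 7), function(z)
    list(com = c(3.5, 3.5, z), R = diag(3)))
  tr <- pose_trajectory(body, bil, poses)
  s <- com_z_distance_series(tr)
  expect_equal(s$values[1], 4)
  expect_true(all(diff(s$values) <= 0))
  expect_equal(s$values, tr$com[, 3] - bil$plane_z)
})

test_that("density map conserves mass and localises identical frames", {
  pool <- data.frame(traj = 1, frame = 1:50, time = 1:50,
                     distance = rep(2.13, 50), rzz = rep(0.42, 50))
  map <- density_map(pool)
  area <- 0.1 * 0.05
  expect_equal(sum(map$density) * area, 1, tolerance = 1e-9)
  expect_equal(sum(map$counts > 0), 1L)

  set.seed(11)
  pool2 <- data.frame(
    traj = 1, frame = 1:400, time = 1:400,
    distance = c(stats::rnorm(200, 3.3, 0.05), stats::rnorm(200, 3.6, 0.05)),
    rzz = pmin(1, pmax(-1, c(stats::rnorm(200, 0.9, 0.02),
                             stats::rnorm(200, -0.8, 0.02))))
  )
  map2 <- density_map(pool2)
  expect_equal(sum(map2$density) * area, 1, tolerance = 1e-9)
  modes <- detect_modes(map2, distance_bound = 5, min_occupancy = 0.02)
  expect_length(modes, 2L)
  centers <- do.call(rbind, lapply(modes, `[[`, "center"))
  centers <- centers[order(centers[, "rzz"], decreasing = TRUE), ]
  expect_lt(abs(centers[1, "distance"] - 3.3), 0.1)
  expect_lt(abs(centers[1, "rzz"] - 0.9), 0.05)
  expect_lt(abs(centers[2, "distance"] - 3.6), 0.1)
  expect_lt(abs(centers[2, "rzz"] + 0.8), 0.05)
  expect_lte(sum(vapply(modes, `[[`, numeric(1), "occupancy")), 1 + 1e-12)
})

test_that("uniform maps above the occupancy floor yield no modes", {
  set.seed(12)
  pool <- data.frame(traj = 1, frame = 1:2000, time = 1:2000,
                     distance = stats::runif(2000, 0, 4),
                     rzz = stats::runif(2000, -1, 1))
  map <- density_map(pool)
  expect_length(detect_modes(map, distance_bound = 4, min_occupancy = 0.05),
                0L)
})

test_that("re-referencing maps the representative frame to Rzz = 1", {
  body <- c2_body()
  bil <- build_bilayer(40, std_fracs, mode = "mean-field")
  params <- sim_params()
  trajs <- lapply(1:3, function(i) {
    st <- init_system(body, bil, 2.5, seed = 40 + i)
    simulate_bd(st, params, 400, record_every = 10, seed = 40 + i)
  })
  ref <- reference_from_ensemble(trajs)
  pool <- pose_ensemble(trajs, ref)
  map <- density_map(pool)
  modes <- detect_modes(map, distance_bound = 10, min_occupancy = 0.01)
  expect_gt(length(modes), 0)
  mode <- modes[[which.max(vapply(modes, `[[`, numeric(1), "occupancy"))]]
  rr <- rereference(trajs, mode)
  rf <- mode$representative_frame
  expect_equal(rr[[rf$traj]]$rzz[rf$frame], 1, tolerance = 1e-9)
  # idempotent: re-referencing again with the same frame changes nothing
  rr2 <- rereference(trajs, mode)
  expect_equal(rr[[1]]$rzz, rr2[[1]]$rzz, tolerance = 1e-12)
  # composition: equals series computed from scratch with the new reference
  new_ref <- membind:::frame_bead_coords(trajs[[rf$traj]], rf$frame)
  direct <- rzz_series(trajs[[2]], new_ref)
  expect_equal(rr[[2]]$rzz, direct$rzz, tolerance = 1e-12)
})

test_that("mode scoring evaluates geometric predicates on the frame", {
  body <- c2_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field")
  # buried pose: termini (body-frame +z face) point INTO the membrane
  poses <- c(
    lapply(1:30, function(i) list(com = c(3.5, 3.5, 1.0),
                                  R = rotation_about("x", pi))),
    lapply(1:10, function(i) list(com = c(3.5, 3.5, 1.2), R = diag(3)))
  )
  tr <- pose_trajectory(body, bil, poses)
  pool <- pose_ensemble(list(tr), membind:::frame_bead_coords(tr, 1))
  modes <- detect_modes(density_map(pool), distance_bound = 3,
                        min_occupancy = 0.02)
  scored <- score_modes(
    modes, list(tr),
    physical_mask = list(list(labels = "terminus", min_z = 0.5)),
    productive_mask = list(list(labels = "basic", max_z = 1.5))
  )
  # frames 1-30 hold the flipped pose (termini down), 31-40 the upright one;
  # note the reference frame is itself the flipped pose
  rep_frames <- vapply(scored, function(m) m$representative_frame$frame,
                       numeric(1))
  flipped <- which(rep_frames <= 30)
  upright <- which(rep_frames > 30)
  expect_false(scored[[flipped]]$flags$physical) # termini buried
  expect_true(scored[[upright]]$flags$physical)
  expect_true(scored[[upright]]$flags$productive)
  # empty masks are vacuously true
  plain <- score_modes(modes, list(tr))
  expect_true(all(vapply(plain, function(m) m$flags$physical, logical(1))))
  expect_error(score_modes(modes, list(tr),
                           physical_mask = list(list(labels = "nope",
                                                     min_z = 1))),
               "unknown bead label")
  # brute-force check of the productive predicate on the upright frame
  rf <- scored[[upright]]$representative_frame
  xyz <- membind:::frame_bead_coords(tr, rf$frame)
  expect_equal(
    all(xyz[body$bead_labels == "basic", 3] <= 1.5),
    scored[[upright]]$flags$productive
  )
})

test_that("refinement classification: retained / rotated / unbound", {
  body <- c2_body()
  bil <- build_bilayer(10, c(PC = 1), seed = 2)
  static <- pose_trajectory(body, bil,
                            lapply(1:10, function(i)
                              list(com = c(3.5, 3.5, 1), R = diag(3))))
  cls <- classify_refinement(static)
  expect_equal(cls$label, "retained")
  expect_equal(cls$max_delta_distance, 0)
  expect_equal(cls$max_delta_angle, 0, tolerance = 1e-6)

  rotated <- pose_trajectory(body, bil, c(
    list(list(com = c(3.5, 3.5, 1), R = diag(3))),
    lapply(seq(0.1, pi / 2, length.out = 9), function(a)
      list(com = c(3.5, 3.5, 1), R = rotation_about("y", a)))
  ))
  cls2 <- classify_refinement(rotated)
  expect_equal(cls2$label, "rotated")
  expect_equal(cls2$max_delta_angle, 90, tolerance = 1e-6)

  escape <- pose_trajectory(body, bil, lapply(
    c(1, 1, seq(2, 8, length.out = 8)), function(z)
      list(com = c(3.5, 3.5, z), R = diag(3))
  ))
  cls3 <- classify_refinement(escape)
  expect_equal(cls3$label, "unbound")
  expect_equal(cls3$max_delta_distance, 7)

  # manual labels on constructed trajectories
  wiggle <- pose_trajectory(body, bil, lapply(1:10, function(i)
    list(com = c(3.5, 3.5, 1 + 0.1 * (i %% 2)),
         R = rotation_about("y", 0.2 * (i %% 3)))))
  expect_equal(classify_refinement(wiggle)$label, "retained")
})
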