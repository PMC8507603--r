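# Synthetic-data generator: bilayer composition, initial placement, energy
# model, Brownian dynamics, and the window generators' statistical behaviour.

test_that("bilayer composition uses largest-remainder allocation", {
  b <- build_bilayer(80, std_fracs, seed = 1)
  expect_equal(unname(b$species_counts[c("PC", "PS", "PIP2")]),
               c(64L, 12L, 4L))
  expect_equal(2 * b$species_counts[["PIP2"]], 8) # 8 PIP2 per bilayer
  expect_equal(unname(build_bilayer(100, c(PC = 1))$species_counts), 100L)
  # 81 lipids at 80:15:5 -> floors (64,12,4)=80, largest remainder adds 1 PC
  b81 <- build_bilayer(81, std_fracs, seed = 1)
  expect_equal(unname(b81$species_counts[c("PC", "PS", "PIP2")]),
               c(65L, 12L, 4L))
  expect_equal(sum(b81$species_counts), 81)
})

test_that("invalid compositions are rejected", {
  expect_error(build_bilayer(80, c(PC = 0.9, PS = -0.1, PIP2 = 0.2)),
               "negative")
  expect_error(build_bilayer(80, c(PC = 0.8, PS = 0.1)), "sum to 1")
})

test_that("bilayer placement is reproducible and inside the box", {
  b1 <- build_bilayer(50, std_fracs, box_xy = c(7, 7), seed = 9)
  b2 <- build_bilayer(50, std_fracs, box_xy = c(7, 7), seed = 9)
  expect_identical(b1$lipid_xy, b2$lipid_xy)
  expect_true(all(b1$lipid_xy >= 0 & b1$lipid_xy <= 7))
})

test_that("init_system is deterministic and honours the minimum separation", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, seed = 1)
  s1 <- init_system(body, bil, 4.4, seed = 5)
  s2 <- init_system(body, bil, 4.4, seed = 5)
  expect_identical(s1$body_orientation, s2$body_orientation)
  xyz <- membind:::state_bead_coords(s1)
  expect_equal(min(xyz[, 3]) - bil$plane_z, 4.4, tolerance = 1e-12)
  # different seeds give different orientations
  expect_false(isTRUE(all.equal(
    s1$body_orientation, init_system(body, bil, 4.4, seed = 6)$body_orientation
  )))
})

test_that("random initial orientations are uniform on the rotation group", {
  body <- c2_body()
  bil <- build_bilayer(10, c(PC = 1), seed = 1, mode = "mean-field")
  ref <- body$bead_positions
  set.seed(42)
  rzz <- vapply(seq_len(10000), function(i) {
    q <- as.numeric(random_quaternion(1))
    quat_to_matrix(q)[3, 3]
  }, numeric(1))
  # uniform rotations map the body z axis uniformly on the sphere: Rzz ~ U[-1,1]
  ks <- suppressWarnings(stats::ks.test(rzz, "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("potential energy: neutral body far above the wall is ~0", {
  body <- tiny_body()
  bil <- build_bilayer(40, std_fracs, seed = 2)
  st <- system_state(body, bil, c(3.5, 3.5, 5))
  expect_lt(abs(potential_energy(st, sim_params())), 1e-10)
})

test_that("mean-field energy has the exponential form", {
  body <- tiny_body(charges = c(1, 0, 0, 0))
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  params <- sim_params(wall_stiffness = 1e-12) # isolate the electrostatics
  lam <- params$debye_length
  u1 <- potential_energy(system_state(body, bil, c(1, 1, 2)), params)
  u2 <- potential_energy(system_state(body, bil, c(1, 1, 2 + lam)), params)
  expect_equal(u1 / u2, exp(1), tolerance = 1e-4)
})

test_that("explicit lipids smeared over a fine grid converge to mean-field", {
  # A large box is needed so the minimum-image sum approximates the full
  # plane integral the mean-field expression is derived from.
  body <- tiny_body(charges = c(2, 1, 0, -1))
  box <- 40
  bil_mf <- build_bilayer(80, std_fracs, box_xy = c(box, box),
                          mode = "mean-field")
  sigma <- membind:::surface_charge_density(bil_mf)
  u_mf <- potential_energy(system_state(body, bil_mf, c(box / 2, box / 2, 1.5)),
                           sim_params(wall_stiffness = 1e-12))
  err <- vapply(c(40, 80, 160), function(n) {
    g <- (seq_len(n) - 0.5) * box / n
    bil <- build_bilayer(n * n, c(GRID = 1), box_xy = c(box, box),
                         species_charges = c(GRID = sigma * box^2 / n^2))
    bil$lipid_xy <- as.matrix(expand.grid(g, g))
    u <- potential_energy(system_state(body, bil, c(box / 2, box / 2, 1.5)),
                          sim_params(wall_stiffness = 1e-12,
                                     core_radius = 1e-6))
    abs(u - u_mf) / abs(u_mf)
  }, numeric(1))
  expect_lt(err[3], 0.01)
  expect_true(all(err < 0.01))
})

test_that("lambda outside [0,1] and non-PIP2 tags are rejected", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, seed = 1)
  st <- system_state(body, bil, c(3.5, 3.5, 1))
  pip2 <- which(bil$lipid_species == "PIP2")[1]
  pc <- which(bil$lipid_species == "PC")[1]
  expect_error(potential_energy(st, sim_params(), lambda = 1.2,
                                tagged_lipid = pip2), "lambda")
  expect_error(potential_energy(st, sim_params(), lambda = 0.5,
                                tagged_lipid = pc), "invalid tag")
  expect_error(generate_lambda_set(st, sim_params(), 5, pc, 10), "invalid tag")
})

test_that("alchemical coupling scales the tagged lipid linearly", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, seed = 1)
  st <- system_state(body, bil, c(3.5, 3.5, 1))
  pip2 <- which(bil$lipid_species == "PIP2")[1]
  u0 <- potential_energy(st, sim_params(), lambda = 0, tagged_lipid = pip2)
  u1 <- potential_energy(st, sim_params(), lambda = 1, tagged_lipid = pip2)
  uh <- potential_energy(st, sim_params(), lambda = 0.5, tagged_lipid = pip2)
  expect_equal(uh, (u0 + u1) / 2, tolerance = 1e-12)
})

test_that("near-zero temperature with no forces leaves the state unchanged", {
  body <- tiny_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 6))
  params <- sim_params(temperature = 1e-6, diff_trans = 1e-20,
                       diff_rot = 1e-20, diff_lipid = 1e-20)
  tr <- simulate_bd(st, params, n_steps = 50, seed = 1)
  expect_equal(tr$com[nrow(tr$com), ], st$body_com, tolerance = 1e-6)
  expect_equal(tr$quat[nrow(tr$quat), ], st$body_orientation,
               tolerance = 1e-6)
})

test_that("identical seeds give bitwise-identical trajectories", {
  body <- c2_body()
  bil <- build_bilayer(40, std_fracs, seed = 2)
  st <- init_system(body, bil, 4.4, seed = 3)
  t1 <- simulate_bd(st, sim_params(), 200, record_every = 10, seed = 7)
  t2 <- simulate_bd(st, sim_params(), 200, record_every = 10, seed = 7)
  expect_identical(t1$com, t2$com)
  expect_identical(t1$quat, t2$quat)
  expect_identical(t1$lipid_xy, t2$lipid_xy)
})

test_that("lipids stay inside the periodic box during dynamics", {
  body <- c2_body()
  bil <- build_bilayer(40, std_fracs, seed = 2)
  st <- system_state(body, bil, c(3.5, 3.5, 1.2))
  tr <- simulate_bd(st, sim_params(), 400, record_every = 20,
                    move_body = FALSE, seed = 8)
  expect_true(all(tr$lipid_xy[, , 1] >= 0 & tr$lipid_xy[, , 1] < 7))
  expect_true(all(tr$lipid_xy[, , 2] >= 0 & tr$lipid_xy[, , 2] < 7))
})

test_that("an over-large timestep raises an instability error", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 0.75)) # deep in the wall
  expect_error(
    simulate_bd(st, sim_params(timestep = 50), 100, seed = 1),
    "instability"
  )
})

test_that("harmonic restraint reproduces equipartition variance kT/k", {
  body <- tiny_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 5))
  params <- sim_params(timestep = 0.0027) # theta*dt ~ 0.02 for k = 2000
  tr <- simulate_bd(st, params, n_steps = 1e5, record_every = 5,
                    restraint = list(k = 2000, center = 5), seed = 42)
  v <- stats::var(tr$com[-(1:200), 3])
  expect_equal(v, kt_kj(323) / 2000, tolerance = 0.05)
})

test_that("free rotational diffusion samples orientations uniformly", {
  body <- tiny_body()
  bil <- build_bilayer(10, c(PC = 1), mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 6))
  params <- sim_params(diff_rot = 1) # fast orientational mixing
  tr <- simulate_bd(st, params, n_steps = 30000, record_every = 50, seed = 11)
  rzz <- vapply(seq_len(nrow(tr$quat)), function(i)
    quat_to_matrix(tr$quat[i, ])[3, 3], numeric(1))
  ks <- suppressWarnings(stats::ks.test(rzz[-(1:50)], "punif", -1, 1))
  expect_gt(ks$p.value, 0.01)
})

test_that("Boltzmann consistency: unbiased sampling matches the analytic PMF", {
  body <- c2_body()
  bil <- build_bilayer(80, c(PC = 0.8, PS = 0.2), mode = "mean-field")
  params <- sim_params(upper_wall_distance = 2.5, upper_wall_k = 500)
  st <- system_state(body, bil, c(3.5, 3.5, 1.3))
  tr <- simulate_bd(st, params, n_steps = 2e5, record_every = 5,
                    move_orientation = FALSE, upper_wall = TRUE, seed = 13)
  z <- tr$com[-(1:2000), 3]
  h <- 0.05
  edges <- seq(0.8, 2.2, by = h)
  cnt <- tabulate(findInterval(z, edges), nbins = length(edges) - 1)
  mids <- edges[-1] - h / 2
  keep <- cnt > 500 & mids < 2 # well region, away from the upper wall
  kt <- kt_kj(params$temperature)
  g_sim <- -kt * log(cnt[keep] / sum(cnt))
  prof <- analytic_pmf(body, bil, params, seq(0.5, 2.6, by = 0.002),
                       orientation = diag(3))
  gfun <- stats::splinefun(prof$z, prof$g)
  g_ana <- bin_average_potential(gfun, mids[keep], h, kt)
  d <- (g_sim - mean(g_sim)) - (g_ana - mean(g_ana))
  expect_lt(max(abs(d)), 0.5)
})

test_that("charge bookkeeping closes to zero with the neutralizer count", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, seed = 1)
  q_body <- sum(body$bead_charges)
  q_lip <- sum(membind:::lipid_charges(bil))
  q_total <- q_body + q_lip
  n_ions <- abs(q_total)
  # n_ions monovalent counterions of the opposite sign close the system
  expect_equal(q_total - sign(q_total) * n_ions, 0)
  # alchemical neutralizer: PIP2 -> PC frees 5 cations
  expect_equal(counterion_neutralizer_count(-5, 0)$count, 5)
})
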