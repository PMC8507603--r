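# Umbrella-window generation and the WHAM solver.

test_that("stiff-spring windows have sd sqrt(kT/k) and mean at the centre", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 2))
  k <- 2e5
  # the two stiff windows intentionally do not overlap; silence the warning
  win <- suppressWarnings(
    generate_umbrella_windows(st, sim_params(), centers = c(2.0, 2.5),
                              force_constant = k, n_samples = 20000,
                              seed = 4)
  )
  kt <- kt_kj(323)
  for (w in win) {
    expect_equal(mean(w$samples), w$center, tolerance = 2e-3)
    expect_equal(stats::sd(w$samples), sqrt(kt / k), tolerance = 0.03)
  }
})

test_that("windows over an uncharged system are Gaussian about each centre", {
  body <- tiny_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 3))
  win <- generate_umbrella_windows(st, sim_params(), centers = 3.0,
                                   force_constant = 2000, n_samples = 8000,
                                   seed = 5)
  kt <- kt_kj(323)
  s <- win[[1]]$samples
  sdv <- sqrt(kt / 2000)
  br <- stats::qnorm(seq(0.05, 0.95, by = 0.1), 3.0, sdv)
  obs <- tabulate(findInterval(s, br) + 1L, nbins = length(br) + 1)
  expv <- length(s) * diff(c(0, seq(0.05, 0.95, by = 0.1), 1))
  gof <- sum((obs - expv)^2 / expv)
  expect_gt(stats::pchisq(gof, df = length(obs) - 1, lower.tail = FALSE),
            0.01)
})

test_that("the standard 3-7 nm spacing yields ~81 windows", {
  centers <- seq(3, 7, by = 0.05)
  expect_equal(length(centers), 81)
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 4))
  win <- generate_umbrella_windows(st, sim_params(), centers, 2000,
                                   n_samples = 20, seed = 6)
  expect_length(win, 81)
})

test_that("equilibration samples are flagged and skipped by WHAM", {
  w <- umbrella_window(1, 100, c(99, 99, 1:10), n_equil_skipped = 2)
  expect_equal(membind:::window_production(w), as.numeric(1:10))
  expect_error(membind:::window_production(
    umbrella_window(1, 100, c(1, 2), n_equil_skipped = 2)
  ), "no samples")
})

test_that("single unbiased window gives a flat profile", {
  set.seed(1)
  w <- umbrella_window(0.5, 0, stats::runif(50000))
  prof <- wham(list(w), wham_settings(bin_width = 0.1, temperature = 323))
  g <- prof$g[is.finite(prof$g)]
  # spread below 3x binomial noise on -kT log p
  noise <- kt_kj(323) * sqrt(10 / 50000)
  expect_lt(max(abs(g - mean(g))), 3 * noise)
})

test_that("WHAM recovers a known double-well potential", {
  kt <- kt_kj(323)
  u_fun <- function(x) 8 * (x^2 - 1)^2 # kJ/mol double well, minima at +/-1
  k <- 2000
  centers <- seq(-1.6, 1.6, by = 0.05)
  set.seed(2)
  windows <- lapply(centers, function(cen) {
    s <- sample_from_potential(
      function(x) u_fun(x) + 0.5 * k * (x - cen)^2,
      cen - 0.35, cen + 0.35, 5000, kt
    )
    umbrella_window(cen, k, s)
  })
  prof <- wham(windows, wham_settings(bin_width = 0.05, temperature = 323),
               anchor_width = 0.2)
  keep <- is.finite(prof$g)
  g_ref <- bin_average_potential(u_fun, prof$z[keep], 0.05, kt)
  resid <- (prof$g[keep] - mean(prof$g[keep])) - (g_ref - mean(g_ref))
  expect_lt(sqrt(mean(resid^2)), 0.5)
  # well depth of the recovered profile matches the analytic one
  imin <- which.min(prof$g)
  expect_lt(abs(min(prof$g[keep]) - mean(prof$g[keep]) -
                  (min(g_ref) - mean(g_ref))), 0.5)
})

test_that("WHAM is invariant to window duplication and to bias shifts", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 2))
  win <- generate_umbrella_windows(st, sim_params(), seq(1.0, 2.5, 0.05),
                                   2000, n_samples = 2000, seed = 7)
  ws <- wham_settings(temperature = 323)
  p1 <- wham(win, ws)
  p2 <- wham(c(win, win), ws)
  expect_equal(p1$g, p2$g, tolerance = 1e-8)
})

test_that("WHAM matches brute-force maximum likelihood on a discrete system", {
  # 20-bin discrete system with synthetic harmonic biases
  kt <- 1
  mids <- seq(0.05, 1.95, by = 0.1)
  u_true <- 3 * (mids - 1)^2
  centers <- seq(0.2, 1.8, by = 0.4)
  k <- 8
  set.seed(3)
  windows <- lapply(centers, function(cen) {
    p <- exp(-(u_true + 0.5 * k * (mids - cen)^2))
    idx <- sample.int(20, 4000, replace = TRUE, prob = p)
    umbrella_window(cen, k * kt_kj(323), mids[idx]) # k in kJ/mol/nm^2 units
  })
  ws <- wham_settings(bin_width = 0.1, temperature = 323 / 1,
                      tolerance = 1e-10)
  # express kT consistently: use T such that kT = kt_kj(323)
  prof <- wham(windows, ws)
  # brute-force ML: maximise the multinomial likelihood over bin log-probs
  ktj <- kt_kj(323)
  bias <- vapply(centers, function(cen)
    0.5 * k * ktj * (mids - cen)^2 / ktj, numeric(20))
  counts <- vapply(windows, function(w)
    tabulate(findInterval(w$samples, seq(0, 2, 0.1),
                          rightmost.closed = TRUE), nbins = 20), numeric(20))
  nll <- function(logp) {
    lp <- logp - membind:::logsumexp(logp)
    tot <- 0
    for (i in seq_along(centers)) {
      lw <- lp - bias[, i]
      tot <- tot - sum(counts[, i] * (lw - membind:::logsumexp(lw)))
    }
    tot
  }
  opt <- stats::optim(rep(0, 20), nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  p_ml <- exp(opt$par - membind:::logsumexp(opt$par))
  g_ml <- -ktj * log(p_ml)
  keep <- is.finite(prof$g)
  expect_lt(max(abs((prof$g[keep] - mean(prof$g[keep])) -
                      (g_ml[keep] - mean(g_ml[keep])))), 1e-4)
})

test_that("disconnected window chains raise an informative error", {
  w1 <- umbrella_window(0.0, 1000, rnorm(100, 0.0, 0.01))
  w2 <- umbrella_window(5.0, 1000, rnorm(100, 5.0, 0.01))
  expect_error(wham(list(w1, w2), wham_settings(temperature = 323)),
               "disconnected")
})

test_that("bootstrap errors: zero for degenerate samples, ~1/sqrt(n) scaling", {
  # all-identical samples in every window -> zero bootstrap spread
  wdeg <- lapply(c(1, 1.02, 1.04), function(cen)
    umbrella_window(cen, 2000, rep(1.02, 50)))
  ws <- wham_settings(bin_width = 0.05, temperature = 323, n_bootstrap = 10,
                      seed = 1)
  pdeg <- bootstrap_pmf(wdeg, ws)
  expect_true(all(pdeg$g_err[is.finite(pdeg$g)] < 1e-10))

  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 2))
  sizes <- c(250, 1000, 4000)
  errs <- lapply(sizes, function(n) {
    win <- generate_umbrella_windows(st, sim_params(), seq(1.0, 2.0, 0.05),
                                     2000, n_samples = n, seed = 30 + n)
    ws2 <- wham_settings(temperature = 323, n_bootstrap = 30, seed = 2)
    prof <- bootstrap_pmf(win, ws2)
    keep <- is.finite(prof$g) & prof$g_err > 0
    stats::setNames(prof$g_err[keep], round(prof$z[keep], 3))
  })
  zs <- Reduce(intersect, lapply(errs, names))
  m <- vapply(errs, function(v) v[zs], numeric(length(zs)))
  slopes <- apply(log(m), 1, function(r)
    stats::coef(stats::lm(r ~ log(sizes)))[2])
  expect_lt(abs(mean(slopes) + 0.5), 0.1)
  # seeded bootstrap is reproducible
  win <- generate_umbrella_windows(st, sim_params(), seq(1.0, 1.5, 0.05),
                                   2000, n_samples = 500, seed = 31)
  ws3 <- wham_settings(temperature = 323, n_bootstrap = 10, seed = 9)
  expect_identical(bootstrap_pmf(win, ws3)$g_err,
                   bootstrap_pmf(win, ws3)$g_err)
})

test_that("equilibration skip changes the profile by less than its error", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 2))
  win <- generate_umbrella_windows(st, sim_params(), seq(1.0, 2.0, 0.05),
                                   2000, n_samples = 3000, n_equil = 300,
                                   seed = 12)
  ws <- wham_settings(temperature = 323, n_bootstrap = 25, seed = 3)
  p_skip <- bootstrap_pmf(win, ws)
  win_all <- lapply(win, function(w)
    umbrella_window(w$center, w$force_constant, w$samples, 0L))
  p_all <- wham(win_all, ws)
  keep <- is.finite(p_skip$g) & is.finite(p_all$g)
  expect_lt(stats::median(abs(p_skip$g[keep] - p_all$g[keep])),
            3 * stats::median(p_skip$g_err[keep]))
})

test_that("well depth and delta-PMF arithmetic", {
  prof <- structure(list(
    z = seq(1, 4, 0.05),
    g = 48 * ((seq(1, 4, 0.05) - 2)^2 / 2 - 1) * exp(-(seq(1, 4, 0.05) - 2)^2),
    g_err = NULL
  ), class = "pmf_profile")
  prof$g <- prof$g - prof$g[length(prof$g)]
  wd <- well_depth(prof)
  expect_equal(wd$depth, -min(prof$g))
  flat <- structure(list(z = seq(1, 4, 0.05), g = rep(0, 61), g_err = NULL),
                    class = "pmf_profile")
  expect_error(well_depth(flat), "no well")
  # worked examples from the printed tables
  expect_equal(delta_pmf(48.0, 26.0)$value, 22.0)
  expect_equal(delta_pmf(77.7, 27.0)$value, 50.7)
  expect_equal(delta_pmf(50, 50)$value, 0)
  d <- delta_pmf(48.0, 26.0, 1.4, 1.5)
  expect_equal(d$err, sqrt(1.4^2 + 1.5^2))
})

test_that("umbrella windows against the mean-field oracle recover the PMF", {
  body <- c2_body()
  bil <- build_bilayer(80, std_fracs, mode = "mean-field")
  st <- system_state(body, bil, c(3.5, 3.5, 2))
  params <- sim_params()
  win <- generate_umbrella_windows(st, params, seq(0.9, 3.0, 0.05), 2000,
                                   n_samples = 3000, seed = 21)
  prof <- wham(win, wham_settings(bin_width = 0.01, temperature = 323))
  oracle <- analytic_pmf(body, bil, params, seq(0.5, 3.6, by = 0.002),
                         orientation = diag(3))
  gfun <- stats::splinefun(oracle$z, oracle$g)
  keep <- is.finite(prof$g) & prof$n_eff >= 20
  g_ref <- bin_average_potential(gfun, prof$z[keep], 0.01, kt_kj(323))
  resid <- (prof$g[keep] - mean(prof$g[keep])) - (g_ref - mean(g_ref))
  expect_lt(sqrt(mean(resid^2)), 0.5)
})
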