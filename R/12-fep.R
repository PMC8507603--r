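# Alchemical free-energy estimation: pairwise Bennett acceptance ratio,
# self-consistent multistate reweighting (MBAR), bound-minus-free
# differencing, per-lipid totals, counterion bookkeeping and the FEP-vs-dPMF
# consistency report.

#' Bennett acceptance ratio for one state pair
#'
#' Solves the self-consistent BAR equation for the free-energy difference
#' between two states from forward work values u1 - u0 (samples of state 0)
#' and reverse work values u0 - u1 (samples of state 1), both in kT. The
#' overlap diagnostic is the mean Fermi function at the solution; values
#' below 1e-6 raise a poor-overlap error.
#'
#' @param u_forward Reduced work values (kT) for samples of state 0.
#' @param u_reverse Reduced work values (kT) for samples of state 1.
#' @param temperature Kelvin.
#' @return List: `dg` (kJ/mol), `se` (kJ/mol, asymptotic), `overlap`.
#' @export
bar_pair <- function(u_forward, u_reverse, temperature) {
  nf <- length(u_forward)
  nr <- length(u_reverse)
  if (!nf || !nr) stop("both sample sets must be non-empty")
  kt <- kt_kj(temperature)
  m <- log(nf / nr)
  obj <- function(df) {
    # Bennett/MLE self-consistency: forward and reverse Fermi sums balance
    sum(stats::plogis(-(m + u_forward - df))) -
      sum(stats::plogis(m - u_reverse - df))
  }
  lo <- min(-u_reverse, u_forward) - 10
  hi <- max(-u_reverse, u_forward) + 10
  ol <- obj(lo)
  oh <- obj(hi)
  if (ol == 0 && oh == 0) {
    # perfectly symmetric work distributions (e.g. identical states)
    df <- (mean(u_forward) - mean(u_reverse)) / 2
  } else if (ol * oh > 0) {
    stop("poor overlap between states (BAR equation has no root in range)")
  } else {
    df <- stats::uniroot(obj, c(lo, hi), tol = 1e-12)$root
  }
  ff <- stats::plogis(-(m + u_forward - df))
  fr <- stats::plogis(m - u_reverse - df)
  overlap <- (mean(ff) + mean(fr)) / 2
  if (overlap < 1e-6) {
    stop("poor overlap between states (diagnostic < 1e-6)")
  }
  # Bennett's asymptotic variance
  var_df <- (stats::var(ff) / (nf * mean(ff)^2)) +
    (stats::var(fr) / (nr * mean(fr)^2))
  list(dg = kt * df, se = kt * sqrt(var_df), overlap = overlap)
}

#' Multistate free-energy estimation (MBAR)
#'
#' Self-consistent multistate reweighting over all lambda states: iterates
#' f_l = -log sum_n exp(-u_l(x_n) - log sum_k N_k exp(f_k - u_k(x_n)))
#' to convergence, then reports per-state free energies relative to state 1
#' with asymptotic errors from the weight-matrix covariance (SVD form).
#' The endpoint difference f_K - f_1 is the transformation free energy.
#'
#' @param lset A `lambda_window_set`.
#' @param temperature Kelvin (defaults to the set's temperature).
#' @param tol Convergence tolerance on f (kT), default 1e-10.
#' @param max_iter Iteration cap.
#' @return List of class `mbar_result`: `f` (per-state, kJ/mol, f[1] = 0),
#'   `f_err` (kJ/mol vs state 1), `dg` = f[K] (kJ/mol), `dg_err`,
#'   `overlap` (smallest adjacent-state overlap diagnostic).
#' @export
multistate_free_energy <- function(lset, temperature = lset$temperature,
                                   tol = 1e-10, max_iter = 20000) {
  kt <- kt_kj(temperature)
  u <- lset$reduced_potentials # [K sampled, K evaluated, n]
  k <- dim(u)[1]
  n <- dim(u)[3]
  # u_eval[l, j]: sample j (pooled over sampled states) evaluated at state l
  u_eval <- matrix(0, k, k * n)
  for (ks in seq_len(k)) {
    u_eval[, (ks - 1) * n + seq_len(n)] <- u[ks, , ]
  }
  nk <- rep(n, k)
  f <- numeric(k)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # log denominator per sample: log sum_k N_k exp(f_k - u_k(x))
    a <- f + log(nk) - u_eval # k x (k*n)
    amax <- apply(a, 2, max)
    logden <- amax + log(colSums(exp(sweep(a, 2, amax))))
    b <- -u_eval - rep(logden, each = k)
    bmax <- apply(b, 1, max)
    f_new <- -(bmax + log(rowSums(exp(b - bmax))))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter >= max_iter) {
      stop(sprintf("MBAR did not converge (residual %.3g kT)", delta))
    }
  }
  # weight matrix W[j, l] = exp(f_l - u_l(x_j)) / sum_k N_k exp(f_k - u_k(x_j))
  a <- f + log(nk) - u_eval
  amax <- apply(a, 2, max)
  logden <- amax + log(colSums(exp(sweep(a, 2, amax))))
  logw <- t(-u_eval + f) - logden # (k*n) x k
  w <- exp(logw)
  theta <- mbar_covariance(w, nk)
  f_err <- sqrt(pmax(0, diag(theta) + theta[1, 1] - 2 * theta[1, ]))
  # overlap-matrix entries O[l, l+1] = sum_j N_l w_jl w_j,l+1
  overlap <- min(vapply(seq_len(k - 1), function(l) {
    sum(nk[l] * w[, l] * w[, l + 1])
  }, numeric(1)))
  structure(
    list(f = kt * f, f_err = kt * f_err, dg = kt * f[k],
         dg_err = kt * f_err[k], overlap = overlap, n_iter = iter),
    class = "mbar_result"
  )
}

# Eigenvalue/SVD form of the MBAR asymptotic covariance of the f estimates.
mbar_covariance <- function(w, nk) {
  sv <- svd(w)
  sig <- sv$d
  v <- sv$v
  ninner <- diag(sig, length(sig)) %*% t(v) %*% diag(nk, length(nk)) %*%
    v %*% diag(sig, length(sig))
  inner <- diag(length(sig)) - ninner
  inner_inv <- tryCatch(solve(inner), error = function(e) {
    # pseudo-inverse fallback for the singular direction
    ei <- eigen(inner, symmetric = TRUE)
    keep <- abs(ei$values) > 1e-10
    ei$vectors[, keep, drop = FALSE] %*%
      diag(1 / ei$values[keep], sum(keep)) %*%
      t(ei$vectors[, keep, drop = FALSE])
  })
  v %*% diag(sig, length(sig)) %*% inner_inv %*%
    diag(sig, length(sig)) %*% t(v)
}

#' Chained pairwise BAR over a lambda path
#'
#' Adjacent-state BAR estimates accumulated along the lambda schedule; the
#' independent cross-check of [multistate_free_energy()].
#'
#' @param lset A `lambda_window_set`.
#' @param temperature Kelvin.
#' @return List: `dg` (kJ/mol), `se` (quadrature over segments),
#'   `segments` (per-pair results).
#' @export
bar_chain <- function(lset, temperature = lset$temperature) {
  u <- lset$reduced_potentials
  k <- dim(u)[1]
  segs <- lapply(seq_len(k - 1), function(l) {
    bar_pair(
      u_forward = u[l, l + 1, ] - u[l, l, ],
      u_reverse = u[l + 1, l, ] - u[l + 1, l + 1, ],
      temperature = temperature
    )
  })
  list(
    dg = sum(vapply(segs, `[[`, numeric(1), "dg")),
    se = sqrt(sum(vapply(segs, `[[`, numeric(1), "se")^2)),
    segments = segs
  )
}

#' Bound-minus-free free-energy difference of one transformation
#'
#' The reported per-lipid value is dG(bound) - dG(free) for the PIP2 -> PC
#' decharging transformation. In this direction a favourably bound PIP2
#' yields a positive value (removing a favourable interaction costs free
#' energy), matching the sign convention of per-lipid interaction tables;
#' the raw signed value is the same quantity and is retained alongside.
#'
#' @param dg_bound,dg_free Transformation free energies (kJ/mol), numbers or
#'   `mbar_result`s.
#' @param lambdas_bound,lambdas_free Optional lambda schedules; when both
#'   are given they must match.
#' @return List: `reported` (kJ/mol), `raw`, `err` (quadrature if both
#'   inputs carry errors).
#' @export
binding_ddg <- function(dg_bound, dg_free, lambdas_bound = NULL,
                        lambdas_free = NULL) {
  if (!is.null(lambdas_bound) && !is.null(lambdas_free) &&
      !isTRUE(all.equal(lambdas_bound, lambdas_free))) {
    stop("lambda schedule mismatch between bound and free systems")
  }
  eb <- ef <- NA_real_
  if (is.list(dg_bound)) {
    eb <- dg_bound$dg_err
    dg_bound <- dg_bound$dg
  }
  if (is.list(dg_free)) {
    ef <- dg_free$dg_err
    dg_free <- dg_free$dg
  }
  raw <- dg_bound - dg_free
  list(reported = raw, raw = raw,
       err = sqrt(sum(c(eb, ef)^2, na.rm = TRUE)))
}

#' Total alchemical free energy over all transformed lipids
#'
#' @param per_lipid Per-lipid bound-minus-free values (kJ/mol).
#' @param per_lipid_err Optional per-lipid errors (quadrature total).
#' @return List: `total` (kJ/mol), `err`.
#' @export
total_fep <- function(per_lipid, per_lipid_err = NULL) {
  total <- sum(per_lipid)
  err <- if (is.null(per_lipid_err)) NA_real_ else
    sqrt(sum(per_lipid_err^2))
  list(total = total, err = err)
}

#' Monovalent counterions to neutralise an alchemical charge change
#'
#' Changing a head-group charge from `q_initial` to `q_final` (both integer)
#' requires |q_final - q_initial| monovalent counterions to be converted to
#' neutral beads; converting PIP2 (-5) to PC (0) converts five cations.
#'
#' @param q_initial,q_final Integral charges in e.
#' @return List: `count` (integer), `species` ("cation", "anion" or "none").
#' @export
counterion_neutralizer_count <- function(q_initial, q_final) {
  if (abs(q_initial - round(q_initial)) > 1e-9 ||
      abs(q_final - round(q_final)) > 1e-9) {
    stop("charges must be integral")
  }
  dq <- round(q_final) - round(q_initial)
  list(
    count = abs(dq),
    species = if (dq > 0) "cation" else if (dq < 0) "anion" else "none"
  )
}

#' Run the full per-lipid FEP protocol on a bound state
#'
#' For each upper-leaflet PIP2, generates bound and free lambda-window sets
#' (21 states by default), estimates the transformation free energies with
#' MBAR, and differences bound minus free. The whole protocol is repeated
#' `n_repeats` times (default 5) with independent seeds; reported per-lipid
#' values are means over repeats and the total error is the standard
#' deviation of the per-repeat totals.
#'
#' @param state Bound `system_state` (explicit bilayer containing PIP2).
#' @param params `sim_params`.
#' @param n_states Lambda states, default 21.
#' @param n_samples Samples per state, default 400.
#' @param n_repeats Independent repeats, default 5.
#' @param seed Base seed; repeat r, lipid i uses seed + 100 * r + i.
#' @param estimator "mbar" (default) or "bar".
#' @param cache [fep_cache()] defining the z-relaxing bound ensemble
#'   (built from `state` by default).
#' @return Object of class `fep_result`: `per_lipid_ddg`, `per_lipid_err`
#'   (sd over repeats), `total`, `total_err`, `per_repeat_totals`,
#'   `lipid_indices`, `n_repeats`, `estimator`, `overlap_min`,
#'   `neutralizers` (counterion bookkeeping per lipid).
#' @export
run_fep <- function(state, params, n_states = 21, n_samples = 400,
                    n_repeats = 5, seed = 1, estimator = c("mbar", "bar"),
                    cache = fep_cache(state, params)) {
  estimator <- match.arg(estimator)
  lipids <- which(state$bilayer$lipid_species == "PIP2")
  if (!length(lipids)) stop("no PIP2 in the bilayer")
  per_rep <- matrix(0, n_repeats, length(lipids))
  overlap_min <- Inf
  for (r in seq_len(n_repeats)) {
    for (i in seq_along(lipids)) {
      sd_i <- seed + 100 * r + i
      bound <- generate_lambda_set(state, params, n_states, lipids[i],
                                   n_samples, seed = sd_i, cache = cache)
      free <- generate_lambda_set(state, params, n_states, lipids[i],
                                  n_samples, seed = sd_i + 50000,
                                  include_protein = FALSE)
      est <- function(ls) {
        if (estimator == "mbar") {
          multistate_free_energy(ls)
        } else {
          bc <- bar_chain(ls)
          list(dg = bc$dg, dg_err = bc$se, overlap = NA)
        }
      }
      eb <- est(bound)
      ef <- est(free)
      if (estimator == "mbar") overlap_min <- min(overlap_min, eb$overlap)
      per_rep[r, i] <- binding_ddg(eb, ef, bound$lambdas, free$lambdas)$reported
    }
  }
  per_lipid <- colMeans(per_rep)
  totals <- rowSums(per_rep)
  q_pip2 <- state$bilayer$species_charges[["PIP2"]]
  structure(
    list(
      per_lipid_ddg = per_lipid,
      per_lipid_err = apply(per_rep, 2, stats::sd),
      total = sum(per_lipid),
      total_err = stats::sd(totals),
      per_repeat_totals = totals,
      lipid_indices = lipids,
      n_repeats = n_repeats,
      estimator = estimator,
      overlap_min = overlap_min,
      neutralizers = counterion_neutralizer_count(q_pip2, 0)
    ),
    class = "fep_result"
  )
}

#' FEP vs delta-PMF internal consistency report
#'
#' Converting every upper-leaflet PIP2 to PC turns the PIP2 membrane into
#' the PS comparison membrane, so the summed bound-minus-free FEP should
#' match the PMF well-depth difference between the two compositions. The
#' report flags consistency at two combined standard errors.
#'
#' @param fep A `fep_result` (or total in kJ/mol).
#' @param dpmf A [delta_pmf()] result (or value in kJ/mol).
#' @param fep_err,dpmf_err Errors, taken from the objects when omitted.
#' @return List of class `consistency_report`: `total_fep`, `delta_pmf`,
#'   `discrepancy` (fep - dpmf), `combined_error`, `consistent`.
#' @export
fep_pmf_consistency <- function(fep, dpmf, fep_err = NA, dpmf_err = NA) {
  if (is.list(fep)) {
    if (is.na(fep_err)) fep_err <- fep$total_err
    fep <- fep$total
  }
  if (is.list(dpmf)) {
    if (is.na(dpmf_err)) dpmf_err <- dpmf$err
    dpmf <- dpmf$value
  }
  disc <- fep - dpmf
  comb <- sqrt(sum(c(fep_err, dpmf_err)^2, na.rm = TRUE))
  structure(
    list(total_fep = fep, delta_pmf = dpmf, discrepancy = disc,
         combined_error = comb, consistent = abs(disc) <= 2 * comb),
    class = "consistency_report"
  )
}
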