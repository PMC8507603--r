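# Shared constants and small numeric helpers.

#' Boltzmann constant in kJ/mol/K
#'
#' Unit system used throughout: nm, ps, kJ/mol, elementary charges, Kelvin.
#' @export
KB_KJ <- 0.0083145

#' Thermal energy kT in kJ/mol
#' @param temperature Temperature in Kelvin.
#' @return kT in kJ/mol.
#' @export
kt_kj <- function(temperature) {
  stopifnot(is.numeric(temperature), temperature > 0)
  KB_KJ * temperature
}

# Evaluate expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# log(sum(exp(x))) without overflow; x a numeric vector.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix.
logsumexp_rows <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

# Minimum-image displacement in a periodic dimension.
min_image <- function(d, box) {
  d - box * round(d / box)
}

# Wrap coordinates into [0, box).
wrap_box <- function(x, box) {
  x - box * floor(x / box)
}

#' Rotation matrix about a coordinate axis
#'
#' Convenience constructor for proper rotations, used for building reference
#' orientations and in the worked identities of the orientation statistic.
#'
#' @param axis One of "x", "y", "z" or a 3-vector.
#' @param angle Rotation angle in radians.
#' @return A 3x3 proper rotation matrix.
#' @examples
#' rotation_about("x", pi)   # 180 degree flip about the membrane plane x axis
#' @export
rotation_about <- function(axis, angle) {
  u <- if (is.character(axis)) {
    switch(axis,
      x = c(1, 0, 0),
      y = c(0, 1, 0),
      z = c(0, 0, 1),
      stop("unknown axis: ", axis)
    )
  } else {
    axis / sqrt(sum(axis^2))
  }
  c_ <- cos(angle)
  s_ <- sin(angle)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c_ + s_ * ux + (1 - c_) * tcrossprod(u)
}

# Sample n points from a 1D density known on a grid (cell midpoints `x`,
# unnormalized log-density `logp`), exact up to the piecewise-constant proposal
# which is corrected by an independence Metropolis step against `logp_fun`.
# Returns numeric vector of samples.
sample_density_1d <- function(x, logp, n, logp_fun = NULL) {
  stopifnot(length(x) == length(logp), n >= 1)
  dx <- diff(x)
  stopifnot(all(dx > 0), max(dx) - min(dx) < 1e-9 * max(dx))
  h <- dx[1]
  w <- exp(logp - max(logp))
  cells <- sample.int(length(x), size = n, replace = TRUE, prob = w)
  pts <- x[cells] + stats::runif(n, -h / 2, h / 2)
  if (is.null(logp_fun)) {
    return(pts)
  }
  # Independence MH against the exact density, proposal = grid approximation.
  cur <- pts[1]
  lp_cur <- logp_fun(cur)
  lq_cur <- logp[cells[1]]
  out <- numeric(n)
  u <- stats::runif(n)
  lp_prop <- logp_fun(pts)
  for (i in seq_len(n)) {
    lq_prop <- logp[cells[i]]
    log_alpha <- (lp_prop[i] - lp_cur) + (lq_cur - lq_prop)
    if (log(u[i]) < log_alpha) {
      cur <- pts[i]
      lp_cur <- lp_prop[i]
      lq_cur <- lq_prop
    }
    out[i] <- cur
  }
  out
}

# 2D analogue on a periodic box: grid of cell midpoints gx, gy with
# unnormalized log-density matrix logp [length(gx) x length(gy)].
# logp_fun(xy_matrix) returns exact log-density at arbitrary points.
sample_density_2d <- function(gx, gy, logp, n, logp_fun = NULL) {
  hx <- gx[2] - gx[1]
  hy <- gy[2] - gy[1]
  w <- exp(as.vector(logp) - max(logp))
  cells <- sample.int(length(w), size = n, replace = TRUE, prob = w)
  ix <- ((cells - 1L) %% length(gx)) + 1L
  iy <- ((cells - 1L) %/% length(gx)) + 1L
  pts <- cbind(
    gx[ix] + stats::runif(n, -hx / 2, hx / 2),
    gy[iy] + stats::runif(n, -hy / 2, hy / 2)
  )
  if (is.null(logp_fun)) {
    return(pts)
  }
  lp_prop <- logp_fun(pts)
  lq_prop <- logp[cbind(ix, iy)]
  cur <- pts[1, ]
  lp_cur <- lp_prop[1]
  lq_cur <- lq_prop[1]
  out <- matrix(0, n, 2)
  u <- stats::runif(n)
  for (i in seq_len(n)) {
    log_alpha <- (lp_prop[i] - lp_cur) + (lq_cur - lq_prop[i])
    if (log(u[i]) < log_alpha) {
      cur <- pts[i, ]
      lp_cur <- lp_prop[i]
      lq_cur <- lq_prop[i]
    }
    out[i, ] <- cur
  }
  out
}
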