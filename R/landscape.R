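#' Configuration for stochastic landscape construction
#'
#' @param sigma additive noise amplitude (a.u. per sqrt(time)).
#' @param n_trajectories number of Euler-Maruyama trajectories.
#' @param t_burn burn-in time discarded before sampling.
#' @param t_sample sampling duration after burn-in.
#' @param dt_sde SDE time step.
#' @param sample_every record a sample every this many time units.
#' @param seed integer RNG seed; identical configs give identical landscapes.
#' @param xlim,ylim bounds for the two difference coordinates.
#' @param bins number of histogram bins per axis (>= 2).
#' @return An object of class `landscape_config`.
#' @export
landscape_config <- function(sigma = 0.1, n_trajectories = 200, t_burn = 50,
                             t_sample = 500, dt_sde = 0.01,
                             sample_every = 0.5, seed = 1,
                             xlim = c(-1.5, 1.5), ylim = c(-1.5, 1.5),
                             bins = 41) {
  stopifnot(sigma >= 0, dt_sde > 0, bins >= 2, n_trajectories >= 1,
            t_sample > 0)
  structure(list(sigma = sigma, n_trajectories = n_trajectories,
                 t_burn = t_burn, t_sample = t_sample, dt_sde = dt_sde,
                 sample_every = sample_every, seed = as.integer(seed),
                 xlim = xlim, ylim = ylim, bins = bins),
            class = "landscape_config")
}

## vectorized drift over rows of a state matrix, for either model class
.drift_matrix <- function(X, params, mult = 1, multP = 1, r = 0) {
  if (inherits(params, "wavepin_params")) {
    p <- params
    Xa <- X[, 1]; Xp <- X[, 2]
    Xc <- p$rhoX - p$psi * (Xa + Xp) / 2
    g <- mult * p$gamma
    cbind(p$Dtilde * (Xp - Xa) + p$kon * Xc - p$koff * Xa +
            g * Xc * Xa^p$n / (p$K^p$n + Xa^p$n) + r * Xp,
          p$Dtilde * (Xa - Xp) + p$kon * Xc - p$koff * Xp +
            g * Xc * Xp^p$n / (p$K^p$n + Xp^p$n) - r * Xp)
  } else {
    p <- params
    Aa <- X[, 1]; Ap <- X[, 2]; Pa <- X[, 3]; Pp <- X[, 4]
    Ac <- p$rhoA - p$psi * (Aa + Ap) / 2
    Pc <- p$rhoP - p$psi * (Pa + Pp) / 2
    kAP <- mult * p$kAP; kPA <- multP * p$kPA
    cbind(p$Dtilde * (Ap - Aa) + p$kon * Ac - p$koff * Aa -
            kAP * Pa^p$alpha * Aa + r * Ap,
          p$Dtilde * (Aa - Ap) + p$kon * Ac - p$koff * Ap -
            kAP * Pp^p$alpha * Ap - r * Ap,
          p$Dtilde * (Pp - Pa) + p$kon * Pc - p$koff * Pa -
            kPA * Aa^p$beta * Pa,
          p$Dtilde * (Pa - Pp) + p$kon * Pc - p$koff * Pp -
            kPA * Ap^p$beta * Pp)
  }
}

#' Euler-Maruyama ensemble of the PAR (or wave-pinning) model
#'
#' Integrates `dX = f(X) dt + sigma * sqrt(dt) * xi` for an ensemble of
#' trajectories, with reflection at zero to preserve nonnegativity, and
#' returns states sampled after burn-in. Fully reproducible given
#' `config$seed`.
#'
#' @param params an `ode_params` or `wavepin_params` object.
#' @param schedule a `feedback_schedule` (evaluated at each step time).
#' @param cue a `polarity_cue` or `NULL`.
#' @param config a `landscape_config`.
#' @param initial_states matrix of initial states (one row per trajectory,
#'   recycled as needed). Default: stable fixed points of the model at the
#'   schedule's initial multiplier, tiled across trajectories; falls back to
#'   the uniform no-feedback balance if none are stable.
#' @return A matrix of sampled states (rows = samples), with attribute
#'   `"times"`; 4 columns for the PAR model, 2 for wave-pinning.
#' @export
euler_maruyama_ensemble <- function(params, schedule = constant_schedule(),
                                    cue = NULL, config = landscape_config(),
                                    initial_states = NULL) {
  d <- if (inherits(params, "wavepin_params")) 2L else 4L
  n <- config$n_trajectories
  if (is.null(initial_states)) {
    m0 <- schedule_multiplier(schedule, 0)
    fp <- if (d == 2) wavepin_fixed_points(params, multiplier = m0)
          else find_steady_states(params, multiplier = m0)
    fp <- fp[fp$stability == "stable", seq_len(d), drop = FALSE]
    if (nrow(fp) == 0) {
      bal <- params$kon * (if (d == 2) params$rhoX else
        max(params$rhoA, params$rhoP)) /
        (params$koff + params$kon * params$psi)
      fp <- matrix(bal, 1, d)
    }
    initial_states <- as.matrix(fp)
  }
  X <- initial_states[rep_len(seq_len(nrow(initial_states)), n), ,
                      drop = FALSE]
  dt <- config$dt_sde
  sig_dt <- config$sigma * sqrt(dt)
  n_steps <- ceiling((config$t_burn + config$t_sample) / dt)
  rec_stride <- max(1L, round(config$sample_every / dt))
  burn_steps <- ceiling(config$t_burn / dt)
  set.seed(config$seed)
  samples <- vector("list", (n_steps - burn_steps) %/% rec_stride + 1L)
  times <- numeric(0)
  k <- 0L
  drift_warned <- FALSE
  scale0 <- max(abs(X)) + 1
  for (s in seq_len(n_steps)) {
    t <- (s - 1) * dt
    m <- schedule_multiplier(schedule, t)
    mP <- if (schedule$apply_to_kPA) m else 1
    f <- .drift_matrix(X, params, m, mP, cue_rate(cue, t))
    if (!drift_warned && max(abs(f)) * dt > 0.2 * scale0) {
      warning("SDE step size: drift per step exceeds 20% of state scale")
      drift_warned <- TRUE
    }
    X <- X + f * dt + matrix(stats::rnorm(n * d, sd = sig_dt), n, d)
    X <- abs(X)  # reflect at zero
    if (s > burn_steps && (s - burn_steps) %% rec_stride == 0L) {
      k <- k + 1L
      samples[[k]] <- X
      times <- c(times, t + dt)
    }
  }
  out <- do.call(rbind, samples[seq_len(k)])
  colnames(out) <- if (d == 2) c("Xa", "Xp") else .state_names
  attr(out, "times") <- times
  out
}

#' Project PAR states onto the difference coordinates
#'
#' @param states matrix with columns `Aa, Ap, Pa, Pp` (or a 2-column matrix,
#'   returned unchanged).
#' @return Two-column matrix `(Aa - Pa, Ap - Pp)`.
#' @export
project_differences <- function(states) {
  if (ncol(states) == 2) return(states)
  cbind(anterior = states[, "Aa"] - states[, "Pa"],
        posterior = states[, "Ap"] - states[, "Pp"])
}

#' Build an occupancy landscape from sampled states
#'
#' Histograms the 2D projection of the samples and converts occupancy into a
#' quasipotential `U = -log(density)`, shifted so that `min(U) == 0`.
#' Unoccupied bins carry `NA` rather than an arbitrary large value.
#'
#' @param samples matrix of sampled states (4-column PAR states are projected
#'   onto the difference coordinates; 2-column input is used as-is).
#' @param config a `landscape_config` supplying grid bounds and bin count.
#' @param min_samples minimum sample count required.
#' @return An object of class `landscape_grid`: list with `x`, `y` (bin
#'   centers), `density` (sums to 1 over occupied bins), `U`, `counts`.
#' @export
build_landscape <- function(samples, config = landscape_config(),
                            min_samples = 100) {
  pts <- project_differences(samples)
  if (nrow(pts) < min_samples)
    stop("too few samples to build a landscape (", nrow(pts), ")")
  bx <- seq(config$xlim[1], config$xlim[2], length.out = config$bins + 1)
  by <- seq(config$ylim[1], config$ylim[2], length.out = config$bins + 1)
  ix <- findInterval(pts[, 1], bx, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], by, rightmost.closed = TRUE)
  keep <- ix >= 1 & ix <= config$bins & iy >= 1 & iy <= config$bins
  counts <- matrix(0, config$bins, config$bins)
  tab <- table(factor(ix[keep], levels = seq_len(config$bins)),
               factor(iy[keep], levels = seq_len(config$bins)))
  counts[] <- as.numeric(tab)
  density <- counts / sum(counts)
  U <- -log(density)
  U[!is.finite(U)] <- NA_real_
  U <- U - min(U, na.rm = TRUE)
  structure(list(x = (bx[-1] + bx[-length(bx)]) / 2,
                 y = (by[-1] + by[-length(by)]) / 2,
                 density = density, U = U, counts = counts),
            class = "landscape_grid")
}

#' Local minima of a quasipotential grid
#'
#' A bin is a candidate minimum if its `U` is no greater than that of all its
#' 8-neighbors, it holds at least `min_count` samples, and at least
#' `min_neighbors` of its neighbors are occupied (screening out isolated
#' excursion bins). Candidates within `suppress_radius` bins of a
#' lower-`U` minimum are merged into it.
#'
#' @param grid a `landscape_grid`.
#' @param min_count minimum sample count in a minimum bin; default
#'   `max(5, 0.1%)` of all samples.
#' @param min_neighbors minimum occupied 8-neighbors.
#' @param suppress_radius Chebyshev merge radius in bins.
#' @return data.frame with bin-center coordinates `x`, `y`, `U` and `count`,
#'   ordered by increasing `U`.
#' @export
landscape_minima <- function(grid, min_count = NULL, min_neighbors = 5,
                             suppress_radius = 2) {
  if (is.null(min_count))
    min_count <- max(5, 1e-3 * sum(grid$counts))
  U <- grid$U
  nb <- dim(U)
  res <- list()
  for (i in seq_len(nb[1])) for (j in seq_len(nb[2])) {
    if (is.na(U[i, j]) || grid$counts[i, j] < min_count) next
    ngb <- U[max(1, i - 1):min(nb[1], i + 1),
             max(1, j - 1):min(nb[2], j + 1)]
    if (sum(!is.na(ngb)) - 1 < min_neighbors) next
    if (U[i, j] <= min(ngb, na.rm = TRUE) + 1e-12)
      res[[length(res) + 1]] <- data.frame(i = i, j = j, x = grid$x[i],
                                           y = grid$y[j], U = U[i, j],
                                           count = grid$counts[i, j])
  }
  if (length(res) == 0)
    return(data.frame(x = numeric(0), y = numeric(0), U = numeric(0),
                      count = numeric(0)))
  cand <- do.call(rbind, res)
  cand <- cand[order(cand$U), ]
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!any(keep)) { keep[k] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    if (min(pmax(abs(prev$i - cand$i[k]), abs(prev$j - cand$j[k]))) >
        suppress_radius)
      keep[k] <- TRUE
  }
  cand <- cand[keep, c("x", "y", "U", "count")]
  rownames(cand) <- NULL
  cand
}

#' Deterministic velocity field on the difference-coordinate grid
#'
#' The 2D projection of the four-variable flow is degenerate: each grid point
#' maps to many full states. The default lift places each point on the
#' symmetric section where the compartment sums `Aa + Pa` and `Ap + Pp` equal
#' a reference value (taken from the central fixed point unless given), and
#' the velocity is the projection `(dAa - dPa, dAp - dPp)` of the rhs there.
#'
#' @param params an `ode_params` object.
#' @param multiplier,multiplier_kPA feedback multipliers.
#' @param cue_rate constant cue rate.
#' @param grid_x,grid_y coordinate vectors for the difference coordinates.
#' @param section_sum reference compartment sum for the lift; default
#'   `2 * central fixed-point concentration` under the no-feedback balance.
#' @return List with `x`, `y`, and matrices `vx`, `vy`.
#' @export
velocity_field <- function(params, multiplier = 1, multiplier_kPA = 1,
                           cue_rate = 0, grid_x, grid_y,
                           section_sum = NULL) {
  if (is.null(section_sum)) {
    bal <- params$kon * max(params$rhoA, params$rhoP) /
      (params$koff + params$kon * params$psi)
    section_sum <- 2 * bal
  }
  vx <- matrix(NA_real_, length(grid_x), length(grid_y))
  vy <- vx
  for (i in seq_along(grid_x)) for (j in seq_along(grid_y)) {
    da <- grid_x[i]; dp <- grid_y[j]
    st <- c(Aa = (section_sum + da) / 2, Ap = (section_sum + dp) / 2,
            Pa = (section_sum - da) / 2, Pp = (section_sum - dp) / 2)
    if (any(st < 0)) next
    if (params$rhoA - params$psi * (st[1] + st[2]) / 2 < 0 ||
        params$rhoP - params$psi * (st[3] + st[4]) / 2 < 0) next
    f <- .drift_matrix(matrix(st, 1), params, multiplier, multiplier_kPA,
                       cue_rate)
    vx[i, j] <- f[1] - f[3]
    vy[i, j] <- f[2] - f[4]
  }
  list(x = grid_x, y = grid_y, vx = vx, vy = vy)
}

#' Stationary Fokker-Planck solution on a box
#'
#' Solves the stationary Fokker-Planck equation
#' `0 = -div(f p) + (sigma^2 / 2) * laplacian(p)` with zero-flux (reflecting)
#' boundaries on a rectangular domain, using a Scharfetter-Gummel
#' (exponentially fitted) finite-volume discretization and a sparse direct
#' solve for the null vector, normalized to integrate to 1.
#'
#' @param drift function mapping an `n x d` matrix of positions to an
#'   `n x d` matrix of drift values (`d` = 1 or 2).
#' @param sigma noise amplitude (> 0).
#' @param lower,upper domain bounds (length `d`).
#' @param n grid cells per dimension (scalar or length `d`).
#' @return List with `x` (and `y` for 2D) cell centers, `p` (density, vector
#'   for 1D / matrix for 2D, integrates to 1), and `U = -log(p)` shifted to
#'   min 0.
#' @export
fokker_planck_stationary <- function(drift, sigma, lower, upper, n = 64) {
  stopifnot(sigma > 0, length(lower) == length(upper))
  d <- length(lower)
  n <- rep_len(n, d)
  D <- sigma^2 / 2
  bern <- function(w) ifelse(abs(w) < 1e-10, 1 - w / 2,
                             w / (exp(w) - 1))
  if (d == 1) {
    h <- (upper - lower) / n
    xc <- lower + (seq_len(n) - 0.5) * h
    xf <- lower + seq_len(n - 1) * h           # interior faces
    ff <- drift(matrix(xf, ncol = 1))[, 1]
    w <- ff * h / D
    # flux over face i: (D/h) * (B(-w) p_i - B(w) p_{i+1})
    lo <- (D / h) * bern(-w)
    hi <- (D / h) * bern(w)
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      # d p_i/dt -= flux_i / h ; d p_{i+1}/dt += flux_i / h
      A[i, i] <- A[i, i] - lo[i] / h
      A[i, i + 1] <- A[i, i + 1] + hi[i] / h
      A[i + 1, i] <- A[i + 1, i] + lo[i] / h
      A[i + 1, i + 1] <- A[i + 1, i + 1] - hi[i] / h
    }
    A[1, ] <- 1  # replace one balance equation by the normalization
    b <- c(1, rep(0, n - 1))
    p <- solve(A, b)
    if (min(p) < -1e-8 * max(p)) stop("Fokker-Planck solve did not converge")
    p <- pmax(p, 0)
    p <- p / (sum(p) * h)
    U <- -log(p)
    U <- U - min(U[is.finite(U)])
    return(list(x = xc, p = p, U = U))
  }
  if (d != 2) stop("only 1D and 2D domains are supported")
  hx <- (upper[1] - lower[1]) / n[1]
  hy <- (upper[2] - lower[2]) / n[2]
  xc <- lower[1] + (seq_len(n[1]) - 0.5) * hx
  yc <- lower[2] + (seq_len(n[2]) - 0.5) * hy
  idx <- function(i, j) (j - 1L) * n[1] + i
  N <- n[1] * n[2]
  ii <- integer(0); jj <- integer(0); vv <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  # x-faces between (i,j) and (i+1,j)
  xf <- lower[1] + seq_len(n[1] - 1) * hx
  for (j in seq_len(n[2])) {
    pts <- cbind(xf, rep(yc[j], n[1] - 1))
    fx <- drift(pts)[, 1]
    w <- fx * hx / D
    lo <- (D / hx) * bern(-w); hi <- (D / hx) * bern(w)
    for (i in seq_len(n[1] - 1)) {
      a <- idx(i, j); b2 <- idx(i + 1, j)
      add(a, a, -lo[i] / hx); add(a, b2, hi[i] / hx)
      add(b2, a, lo[i] / hx); add(b2, b2, -hi[i] / hx)
    }
  }
  # y-faces between (i,j) and (i,j+1)
  yf <- lower[2] + seq_len(n[2] - 1) * hy
  for (i in seq_len(n[1])) {
    pts <- cbind(rep(xc[i], n[2] - 1), yf)
    fy <- drift(pts)[, 2]
    w <- fy * hy / D
    lo <- (D / hy) * bern(-w); hi <- (D / hy) * bern(w)
    for (j in seq_len(n[2] - 1)) {
      a <- idx(i, j); b2 <- idx(i, j + 1)
      add(a, a, -lo[j] / hy); add(a, b2, hi[j] / hy)
      add(b2, a, lo[j] / hy); add(b2, b2, -hi[j] / hy)
    }
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(N, N))
  A[1, ] <- 1
  b <- c(1, rep(0, N - 1))
  p <- as.numeric(Matrix::solve(A, b))
  if (min(p) < -1e-8 * max(p)) stop("Fokker-Planck solve did not converge")
  p <- pmax(p, 0)
  p <- p / (sum(p) * hx * hy)
  P <- matrix(p, n[1], n[2])
  U <- -log(P)
  U <- U - min(U[is.finite(U)])
  list(x = xc, y = yc, p = P, U = U)
}

#' Drift function of the wave-pinning model for Fokker-Planck solves
#'
#' @param params a `wavepin_params` object.
#' @param multiplier feedback multiplier on `gamma`.
#' @return A function mapping an `n x 2` matrix of `(Xa, Xp)` states to
#'   drifts, suitable for [fokker_planck_stationary()].
#' @export
wavepin_drift <- function(params, multiplier = 1) {
  force(params); force(multiplier)
  function(X) .drift_matrix(X, params, multiplier)
}
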