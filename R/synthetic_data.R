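#' Ground truth for a synthetic embryo image
#'
#' Describes an elliptical embryo with a membrane of known cross-sectional
#' Gaussian amplitude over a cytoplasmic (error-function) step and a constant
#' background, plus additive Gaussian noise. The amplitude may vary around
#' the contour via `amplitude`, a function of the ellipse parameter angle
#' `theta` (radians; `theta = 0` is the anterior pole at `center + (a, 0)`).
#'
#' @param semi_axes_um ellipse semi-axes (micrometres), anterior-posterior
#'   first.
#' @param pixel_size micrometres per pixel.
#' @param amplitude membrane peak amplitude: a constant or a function of
#'   `theta`.
#' @param cyto cytoplasmic step height (a.u.).
#' @param bg constant background (a.u.).
#' @param membrane_sigma_px Gaussian cross-section width of the membrane
#'   ridge (pixels); the cytoplasmic edge shares this width.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param margin_px image margin beyond the ellipse (pixels).
#' @param seed RNG seed; generation is a pure function of truth + seed.
#' @return An object of class `embryo_truth`.
#' @export
embryo_truth <- function(semi_axes_um = c(25, 15), pixel_size = 0.155,
                         amplitude = 1, cyto = 0.4, bg = 0.1,
                         membrane_sigma_px = 3, noise_sd = 0,
                         margin_px = 60, seed = 1) {
  ampfun <- if (is.function(amplitude)) amplitude
            else function(theta) rep(amplitude, length(theta))
  stopifnot(all(semi_axes_um > 0), pixel_size > 0, membrane_sigma_px > 0,
            noise_sd >= 0, cyto >= 0, bg >= 0)
  structure(list(semi_axes_um = semi_axes_um, pixel_size = pixel_size,
                 amplitude = ampfun, cyto = cyto, bg = bg,
                 membrane_sigma_px = membrane_sigma_px, noise_sd = noise_sd,
                 margin_px = margin_px, seed = as.integer(seed)),
            class = "embryo_truth")
}

## Signed distance to an axis-aligned ellipse (a, b), vectorized Newton on
## the parameter angle of the nearest boundary point. Positive outside.
## Returns list(d = signed distance, theta = parameter of nearest point).
.ellipse_signed_distance <- function(px, py, a, b) {
  t <- atan2(py / b, px / a)
  for (k in 1:30) {
    ct <- cos(t); st <- sin(t)
    dx <- a * ct - px; dy <- b * st - py
    g <- -dx * a * st + dy * b * ct           # d/dt of squared distance / 2
    dg <- (a^2 * st^2 - dx * a * ct) + (b^2 * ct^2 - dy * b * st)
    t <- t - g / pmax(dg, 1e-9)
  }
  ct <- cos(t); st <- sin(t)
  dist <- sqrt((a * ct - px)^2 + (b * st - py)^2)
  inside <- (px / a)^2 + (py / b)^2 < 1
  list(d = ifelse(inside, -dist, dist), theta = t %% (2 * pi))
}

#' Generate a synthetic embryo image with known membrane amplitude
#'
#' Builds the image as `bg + cyto * Phi(-d / sigma) + amp(theta) *
#' exp(-d^2 / (2 sigma^2)) + noise`, where `d` is the signed distance to the
#' elliptical membrane mid-line (positive outside) computed per pixel, and
#' `theta` the parameter angle of the nearest membrane point. The returned
#' ROI traces the ridge center, starting at `theta = 0` (anterior pole) and
#' proceeding so that arc position increases with `theta`.
#'
#' @param truth an `embryo_truth` object.
#' @return List with `img` (numeric matrix), `roi` (`n x 2` matrix of
#'   `(x, y)` coordinates), and `truth_profile` (data.frame `theta`,
#'   `amplitude` — the per-ROI-vertex ground-truth membrane amplitude).
#' @export
make_embryo_image <- function(truth) {
  stopifnot(inherits(truth, "embryo_truth"))
  a <- truth$semi_axes_um[1] / truth$pixel_size
  b <- truth$semi_axes_um[2] / truth$pixel_size
  m <- truth$margin_px
  nc <- ceiling(2 * (a + m)); nr <- ceiling(2 * (b + m))
  cx <- nc / 2; cy <- nr / 2
  if (m < 25) stop("embryo geometry leaves too little margin in the frame")
  xs <- seq_len(nc) - cx
  ys <- seq_len(nr) - cy
  px <- rep(xs, each = nr)
  py <- rep(ys, times = nc)
  sd_ <- .ellipse_signed_distance(px, py, a, b)
  sig <- truth$membrane_sigma_px
  amp <- truth$amplitude(sd_$theta)
  vals <- truth$bg + truth$cyto * stats::pnorm(-sd_$d / sig) +
    amp * exp(-sd_$d^2 / (2 * sig^2))
  img <- matrix(vals, nr, nc)
  set.seed(truth$seed)
  if (truth$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, sd = truth$noise_sd), nr, nc)
  ## ROI along the ridge center at ~1 px arc spacing (ellipse parameter
  ## stepped adaptively: ds = sqrt(a^2 sin^2 + b^2 cos^2) dt)
  per <- .ellipse_perimeter(a, b)
  n_pts <- ceiling(per)
  theta <- .ellipse_arc_params(a, b, n_pts)
  roi <- cbind(x = cx + a * cos(theta), y = cy + b * sin(theta))
  list(img = img, roi = roi,
       truth_profile = data.frame(theta = theta,
                                  amplitude = truth$amplitude(theta)))
}

.ellipse_perimeter <- function(a, b) {
  t <- seq(0, 2 * pi, length.out = 4097)
  sum(sqrt((a * sin(t))^2 + (b * cos(t))^2)[-1] * diff(t))
}

## parameter values giving ~uniform arc-length spacing
.ellipse_arc_params <- function(a, b, n) {
  t <- seq(0, 2 * pi, length.out = 8193)
  ds <- sqrt((a * sin(t))^2 + (b * cos(t))^2)
  s <- cumsum(c(0, (ds[-1] + ds[-length(ds)]) / 2 * diff(t)))
  stats::approx(s, t, xout = seq(0, s[length(s)], length.out = n + 1))$y[-(n + 1)]
}

#' ASI of a membrane profile with the anterior pole at position zero
#'
#' Anterior = the half of the closed contour centered on position 0 (the
#' first and last quarter of rows); posterior = the opposite half.
#'
#' @param values per-position membrane amplitudes (closed contour order,
#'   position 0 first). `NA` values are dropped.
#' @return ASI in `[-0.5, 0.5]`.
#' @export
profile_asi <- function(values) {
  n <- length(values)
  q <- n %/% 4
  ant <- c(seq_len(q), (n - q + 1):n)
  a <- sum(values[ant], na.rm = TRUE)
  p <- sum(values[setdiff(seq_len(n), ant)], na.rm = TRUE)
  asi(a, p)
}

#' Generate a synthetic cluster (punctate) image
#'
#' A sum of 2D Gaussian spots over a constant background with additive
#' Gaussian noise; the ground-truth table is returned alongside.
#'
#' @param n number of clusters (ignored when `positions` given).
#' @param dim image dimensions `c(rows, cols)`.
#' @param positions optional `n x 2` matrix of `(x, y)` centers; default:
#'   seeded uniform positions with pairwise separation >= `min_sep` and
#'   10-pixel borders.
#' @param intensities peak intensities (recycled).
#' @param sigmas spot Gaussian widths in pixels (recycled).
#' @param bg constant background level.
#' @param noise_sd additive Gaussian noise sd.
#' @param min_sep minimum pairwise center separation for random placement.
#' @param seed RNG seed.
#' @return List with `img` and `truth` (data.frame `x`, `y`, `sigma`,
#'   `peak`, `total` — `total` is the analytic integral `2 pi sigma^2 peak`).
#' @export
make_cluster_image <- function(n = 20, dim = c(256, 256), positions = NULL,
                               intensities = 1, sigmas = 2, bg = 0,
                               noise_sd = 0, min_sep = 12, seed = 1) {
  set.seed(seed)
  nr <- dim[1]; nc <- dim[2]
  if (is.null(positions)) {
    positions <- matrix(numeric(0), 0, 2)
    tries <- 0
    while (nrow(positions) < n && tries < 20000) {
      cand <- c(stats::runif(1, 11, nc - 10), stats::runif(1, 11, nr - 10))
      if (nrow(positions) == 0 ||
          min(sqrt(colSums((t(positions) - cand)^2))) >= min_sep)
        positions <- rbind(positions, cand)
      tries <- tries + 1
    }
    if (nrow(positions) < n)
      stop("could not place ", n, " clusters with the requested separation")
  }
  n <- nrow(positions)
  intensities <- rep_len(intensities, n)
  sigmas <- rep_len(sigmas, n)
  img <- matrix(bg, nr, nc)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), times = nc), nr, nc)
  for (i in seq_len(n))
    img <- img + intensities[i] *
      exp(-((xs - positions[i, 1])^2 + (ys - positions[i, 2])^2) /
            (2 * sigmas[i]^2))
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, sd = noise_sd), nr, nc)
  list(img = img,
       truth = data.frame(x = positions[, 1], y = positions[, 2],
                          sigma = sigmas, peak = intensities,
                          total = 2 * pi * sigmas^2 * intensities))
}

#' Ground truth for a cell-cycle-phased membrane-level trace
#'
#' @param t_condensation,t_nebd,t_anaphase strictly increasing phase times:
#'   chromosome condensation (rise onset), nuclear envelope breakdown (peak),
#'   anaphase onset (sharp decline).
#' @param baseline,peak membrane levels before the rise and at NEBD.
#' @param plateau_drop fractional slow decline between NEBD and anaphase
#'   (keeps the argmax uniquely at NEBD).
#' @param fall_time duration of the sharp post-anaphase decline.
#' @param period cycle period for multi-cycle traces (default: single cycle).
#' @param n_cycles number of cell cycles.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return An object of class `oscillation_truth`.
#' @export
oscillation_truth <- function(t_condensation = 5, t_nebd = 12,
                              t_anaphase = 16, baseline = 0.2, peak = 1,
                              plateau_drop = 0.05, fall_time = 1.5,
                              period = NULL, n_cycles = 1, noise_sd = 0,
                              seed = 1) {
  stopifnot(t_condensation < t_nebd, t_nebd < t_anaphase,
            baseline >= 0, peak >= baseline, n_cycles >= 1)
  if (is.null(period)) period <- t_anaphase + fall_time + 4
  stopifnot(period > t_anaphase + fall_time)
  structure(list(t_condensation = t_condensation, t_nebd = t_nebd,
                 t_anaphase = t_anaphase, baseline = baseline, peak = peak,
                 plateau_drop = plateau_drop, fall_time = fall_time,
                 period = period, n_cycles = as.integer(n_cycles),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "oscillation_truth")
}

#' Generate a cell-cycle-phased membrane-level trace
#'
#' Piecewise-linear trace per cycle: baseline before chromosome condensation,
#' rise to the peak at NEBD, slight decline to anaphase onset, sharp drop
#' back to baseline, repeated for `n_cycles`; seeded Gaussian noise added.
#'
#' @param truth an `oscillation_truth`.
#' @param dt sampling interval.
#' @return List with `times`, `levels`, and `phase_marks` (data.frame
#'   `cycle`, `t_condensation`, `t_nebd`, `t_anaphase`).
#' @export
make_oscillation_trace <- function(truth, dt = 0.1) {
  stopifnot(inherits(truth, "oscillation_truth"))
  tr <- truth
  t_end <- tr$period * tr$n_cycles
  times <- seq(0, t_end, by = dt)
  knot_t <- c(0)
  knot_v <- c(tr$baseline)
  marks <- list()
  for (cyc in seq_len(tr$n_cycles)) {
    off <- (cyc - 1) * tr$period
    knot_t <- c(knot_t, off + c(tr$t_condensation, tr$t_nebd, tr$t_anaphase,
                                tr$t_anaphase + tr$fall_time))
    knot_v <- c(knot_v, tr$baseline, tr$peak,
                tr$peak * (1 - tr$plateau_drop), tr$baseline)
    marks[[cyc]] <- data.frame(cycle = cyc,
                               t_condensation = off + tr$t_condensation,
                               t_nebd = off + tr$t_nebd,
                               t_anaphase = off + tr$t_anaphase)
  }
  knot_t <- c(knot_t, t_end + dt)
  knot_v <- c(knot_v, tr$baseline)
  levels <- stats::approx(knot_t, knot_v, xout = times, rule = 2)$y
  set.seed(tr$seed)
  if (tr$noise_sd > 0)
    levels <- levels + stats::rnorm(length(levels), sd = tr$noise_sd)
  list(times = times, levels = levels,
       phase_marks = do.call(rbind, marks))
}

## uniform steady state of the PDE reaction terms with one dominant species
.uniform_steady <- function(params, dominant = c("P", "A")) {
  dominant <- match.arg(dominant)
  p <- params
  balA <- p$konA * p$rhoA / (p$koffA + p$konA * p$psi)
  balP <- p$konP * p$rhoP / (p$koffP + p$konP * p$psi)
  y <- if (dominant == "P") c(A = 0.01 * balA, P = balP)
       else c(A = balA, P = 0.01 * balP)
  f <- function(y) {
    Ac <- p$rhoA - p$psi * y[1]; Pc <- p$rhoP - p$psi * y[2]
    c(p$konA * Ac - p$koffA * y[1] - p$kAP * y[2]^p$alpha * y[1],
      p$konP * Pc - p$koffP * y[2] - p$kPA * y[1]^p$beta * y[2])
  }
  for (k in 1:100) {
    fv <- f(y)
    if (max(abs(fv)) < 1e-12) break
    J <- matrix(0, 2, 2)
    J[1, 1] <- -p$konA * p$psi - p$koffA - p$kAP * y[2]^p$alpha
    J[1, 2] <- -p$kAP * p$alpha * y[2]^(p$alpha - 1) * y[1]
    J[2, 1] <- -p$kPA * p$beta * y[1]^(p$beta - 1) * y[2]
    J[2, 2] <- -p$konP * p$psi - p$koffP - p$kPA * y[1]^p$beta
    y <- pmax(y - solve(J, fv), 0)
  }
  y
}

#' Construct scenario initial profiles
#'
#' Deterministic constructors for the spatial initial conditions of the
#' polarization scenarios (cue-anchored coordinates; see [scenario_spec()]):
#'
#' * `"uniform_P_high"` — pPAR at its uniform-dominant steady level across
#'   the membrane; aPAR mostly cytoplasmic except a furrow-derived Gaussian
#'   bump at the contact (`x = 0`).
#' * `"contact_A_bump"` — the aPAR contact bump alone over near-zero pPAR.
#' * `"reversed_polarized"` — opposing sigmoidal domains with the aPAR
#'   domain at the contact end `x = L` (coarse class `POLARIZED_PA`).
#' * `"uniform_A_high"` — aPAR at its uniform-dominant steady level, pPAR
#'   low (the zygote before symmetry breaking).
#'
#' @param kind scenario profile kind.
#' @param params a `pde_params` object.
#' @param bump_amp,bump_width contact-bump amplitude and Gaussian width
#'   (width defaults to `L / 12`).
#' @param front_width sigmoid front width for `"reversed_polarized"`
#'   (defaults to `L / 30`).
#' @return A `spatial_profile`.
#' @export
make_scenario_profile <- function(kind = c("uniform_P_high", "contact_A_bump",
                                           "reversed_polarized",
                                           "uniform_A_high"),
                                  params = pde_params(), bump_amp = 0.3,
                                  bump_width = NULL, front_width = NULL) {
  kind <- match.arg(kind)
  p <- params
  x <- pde_grid(p)
  L <- p$L
  if (is.null(bump_width)) bump_width <- L / 12
  if (is.null(front_width)) front_width <- L / 30
  bump <- bump_amp * exp(-x^2 / (2 * bump_width^2))
  if (kind == "uniform_P_high") {
    ss <- .uniform_steady(p, "P")
    return(spatial_profile(x, bump, rep(ss[["P"]], p$N)))
  }
  if (kind == "contact_A_bump")
    return(spatial_profile(x, bump, rep(0, p$N)))
  if (kind == "uniform_A_high") {
    ss <- .uniform_steady(p, "A")
    return(spatial_profile(x, rep(ss[["A"]], p$N), rep(ss[["P"]], p$N)))
  }
  ## reversed_polarized: A domain at the contact end x = L
  lvlA <- 1.4 * p$konA * p$rhoA / (p$koffA + p$konA * p$psi)
  lvlP <- 1.4 * p$konP * p$rhoP / (p$koffP + p$konP * p$psi)
  mid <- 0.65 * L
  spatial_profile(x,
                  lvlA / (1 + exp(-(x - mid) / front_width)),
                  lvlP / (1 + exp((x - mid) / front_width)))
}
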