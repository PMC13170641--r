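#' Parameters for the 1D reaction-diffusion PAR model
#'
#' The spatially continuous model on the membrane arc `[0, L]`: both species
#' diffuse along the membrane, exchange with well-mixed cytoplasmic pools
#' driven by the membrane means, and antagonize each other. The P-to-A
#' feedback coefficient is time-varying through `kAP_schedule`; reaction
#' rates may be asymmetric between the species.
#'
#' @param DA,DP membrane diffusivities (length^2/time).
#' @param konA,konP attachment rates (1/time).
#' @param koffA,koffP detachment rates (1/time).
#' @param kAP,kPA antagonism coefficients; `kAP` is scaled by
#'   `kAP_schedule`.
#' @param alpha,beta antagonism exponents.
#' @param rhoA,rhoP total pools.
#' @param psi surface-to-volume ratio.
#' @param L domain length; `N` grid points (>= 16); `dt` time step.
#' @param boundary `"no_flux"` or `"periodic"`.
#' @param kAP_schedule a `feedback_schedule` on `kAP`.
#' @return An object of class `pde_params`.
#' @export
pde_params <- function(DA = 1, DP = 1, konA = 1, konP = 1, koffA = 0.3,
                       koffP = 0.3, kAP = 50, kPA = 50, alpha = 2, beta = 2,
                       rhoA = 1, rhoP = 1, psi = 1, L = 60, N = 128,
                       dt = 0.01, boundary = c("no_flux", "periodic"),
                       kAP_schedule = constant_schedule()) {
  boundary <- match.arg(boundary)
  # N = 2 is admitted so the model can be reduced to the two-compartment ODE
  stopifnot(N >= 2, dt > 0, L > 0)
  dx <- L / N
  if (dt >= dx^2 / (2 * max(DA, DP)))
    stop("dt violates the explicit stability bound dt < dx^2 / (2 max(D))")
  structure(list(DA = DA, DP = DP, konA = konA, konP = konP, koffA = koffA,
                 koffP = koffP, kAP = kAP, kPA = kPA, alpha = alpha,
                 beta = beta, rhoA = rhoA, rhoP = rhoP, psi = psi, L = L,
                 N = as.integer(N), dt = dt, dx = dx, boundary = boundary,
                 kAP_schedule = kAP_schedule),
            class = "pde_params")
}

#' Construct a spatial profile
#'
#' @param x grid positions (cell centers).
#' @param A,P nonnegative concentration vectors, one value per position.
#' @return An object of class `spatial_profile`.
#' @export
spatial_profile <- function(x, A, P) {
  stopifnot(length(x) == length(A), length(A) == length(P),
            all(A >= 0), all(P >= 0))
  structure(list(x = x, A = A, P = P), class = "spatial_profile")
}

#' Grid cell centers of a PDE model
#' @param params a `pde_params` object.
#' @return Numeric vector of length `N`.
#' @export
pde_grid <- function(params) (seq_len(params$N) - 0.5) * params$dx

.laplacian <- function(u, dx, boundary) {
  n <- length(u)
  if (boundary == "periodic")
    (c(u[n], u[-n]) - 2 * u + c(u[-1], u[1])) / dx^2
  else  # no-flux: mirror ghost cells
    (c(u[1], u[-n]) - 2 * u + c(u[-1], u[n])) / dx^2
}

#' Spatially localized cue
#'
#' A cue zone with Gaussian weight `w(x)` centered at `center` with width
#' `width`. In `"attract"` mode, membrane aPAR outside the zone detaches into
#' a redistribution flux deposited inside the zone (total aPAR conserved
#' position-wise): the generic flow/advection bias toward the future
#' anterior. In `"inhibit"` mode, aPAR inside the zone detaches to the
#' cytoplasm at first-order rate `rate * w(x)` (mass conserved through the
#' pool): local inhibition of aPAR activity, as by a contact signal.
#'
#' @param center,width zone center and Gaussian width (same units as `x`).
#' @param rate first-order rate (1/time).
#' @param t_on,t_off active window.
#' @param mode `"attract"` or `"inhibit"`.
#' @return An object of class `spatial_cue`.
#' @export
spatial_cue <- function(center, width, rate, t_on, t_off,
                        mode = c("attract", "inhibit")) {
  mode <- match.arg(mode)
  stopifnot(rate >= 0, width > 0, t_on < t_off)
  structure(list(center = center, width = width, rate = rate, t_on = t_on,
                 t_off = t_off, mode = mode), class = "spatial_cue")
}

.cue_weights <- function(cue, x) exp(-(x - cue$center)^2 / (2 * cue$width^2))

## cue contribution to dA/dt; `r` already gated by the time window
.cue_term <- function(cue, w, A, r) {
  if (r == 0) return(0)
  if (cue$mode == "inhibit") return(-r * w * A)
  rem <- r * (1 - w) * A
  w * (sum(rem) / sum(w)) - rem
}

#' One forward-Euler step of the PDE model
#'
#' Explicit step with central finite differences for diffusion; cytoplasmic
#' pools recomputed from the updated membrane means, so per-species mass is
#' conserved by construction.
#'
#' @param profile a `spatial_profile`.
#' @param params a `pde_params` object.
#' @param t current time (for the feedback schedule and cue window).
#' @param cue a `spatial_cue` or `NULL`.
#' @return The updated `spatial_profile`.
#' @export
pde_step <- function(profile, params, t = 0, cue = NULL) {
  p <- params
  A <- profile$A; P <- profile$P
  m <- schedule_multiplier(p$kAP_schedule, t)
  Ac <- p$rhoA - p$psi * mean(A)
  Pc <- p$rhoP - p$psi * mean(P)
  if (Ac < 0 || Pc < 0) stop("inadmissible pools in PDE state")
  r <- if (is.null(cue)) 0 else
    if (t >= cue$t_on && t <= cue$t_off) cue$rate else 0
  w <- if (is.null(cue)) NULL else .cue_weights(cue, profile$x)
  dA <- p$DA * .laplacian(A, p$dx, p$boundary) + p$konA * Ac -
    p$koffA * A - m * p$kAP * P^p$alpha * A
  if (!is.null(cue)) dA <- dA + .cue_term(cue, w, A, r)
  dP <- p$DP * .laplacian(P, p$dx, p$boundary) + p$konP * Pc -
    p$koffP * P - p$kPA * A^p$beta * P
  A2 <- A + p$dt * dA
  P2 <- P + p$dt * dP
  if (any(A2 < 0) || any(P2 < 0)) {
    warning("concentration clipped at zero after explicit step")
    A2 <- pmax(A2, 0); P2 <- pmax(P2, 0)
  }
  spatial_profile(profile$x, A2, P2)
}

#' Count contiguous domains above a threshold
#'
#' Number of maximal runs of `values > threshold` of length at least
#' `min_width`, with wrap-around merging when `periodic`.
#'
#' @param values numeric profile.
#' @param threshold absolute threshold; default half the profile maximum.
#' @param min_width minimum run length in grid points.
#' @param periodic merge runs across the domain ends.
#' @return Integer domain count.
#' @export
count_domains <- function(values, threshold = NULL, min_width = 2,
                          periodic = FALSE) {
  if (is.null(threshold)) threshold <- 0.5 * max(values)
  above <- values > threshold
  if (!any(above)) return(0L)
  if (all(above)) return(1L)
  r <- rle(above)
  if (periodic && r$values[1] && r$values[length(r$values)]) {
    # merge wrapped run
    r$lengths[1] <- r$lengths[1] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  sum(r$values & r$lengths >= min_width)
}

#' Asymmetry index of a spatial profile
#'
#' `ASI = (A - P) / (2 * (A + P))` with `A` and `P` the summed signal over
#' the anterior (`x < L/2`) and posterior halves; range `[-0.5, 0.5]`.
#'
#' @param values nonnegative profile values on a uniform grid.
#' @return ASI value.
#' @export
asi_of_profile <- function(values) {
  n <- length(values)
  a <- sum(values[seq_len(n %/% 2)])
  p <- sum(values[(n %/% 2 + 1):n])
  asi(a, p)
}

#' Feedback schedule from a pPAR effector membrane trace
#'
#' Rescales a measured (or synthetic) membrane-level time series into a
#' piecewise-linear `kAP` multiplier: the trace maximum maps to 1 (full
#' feedback) and the minimum to `floor`.
#'
#' @param times increasing time points.
#' @param levels nonnegative membrane levels.
#' @param floor multiplier assigned to the trace minimum.
#' @return A `feedback_schedule`.
#' @export
kap_schedule_from_trace <- function(times, levels,
                                    floor = low_feedback_multiplier()) {
  if (length(times) == 0) stop("empty trace")
  stopifnot(length(times) == length(levels), all(levels >= 0))
  if (length(times) == 1) return(feedback_schedule(times, 1))
  rng <- range(levels)
  mult <- if (rng[2] > rng[1])
    floor + (levels - rng[1]) / (rng[2] - rng[1]) * (1 - floor)
  else rep(1, length(levels))
  feedback_schedule(times, mult)
}

#' Scenario specification for P-lineage polarization
#'
#' Bundles an initial profile, a spatially localized cue and a feedback
#' schedule. The built-in scenarios use cue-anchored coordinates in which
#' `x = 0` is the pole where aPAR consolidates in the cue-aligned outcome:
#'
#' * `"P1"` — polarization from a uniform pPAR-high membrane with aPARs
#'   mostly cytoplasmic except a furrow-derived bump at the contact
#'   (`x = 0`); attract-mode cue toward the contact.
#' * `"P2"` — polarity reversal from a reversed-polarized state (aPAR domain
#'   at the contact end `x = L`); inhibit-mode cue at the contact.
#' * `"zygote"` — polarization from the uniform aPAR-high state with an
#'   attract-mode cue toward `x = 0`.
#'
#' @param name `"P1"`, `"P2"` or `"zygote"`.
#' @param params a `pde_params` object (supplies geometry and schedule
#'   defaults; the spec's schedule is taken from `params$kAP_schedule`).
#' @param cue optional `spatial_cue` overriding the scenario default.
#' @param initial optional `spatial_profile` overriding the default.
#' @return An object of class `scenario_spec` with `name`, `initial`, `cue`.
#' @export
scenario_spec <- function(name = c("P1", "P2", "zygote"), params = pde_params(),
                          cue = NULL, initial = NULL) {
  name <- match.arg(name)
  L <- params$L
  if (is.null(initial))
    initial <- switch(name,
      P1 = make_scenario_profile("uniform_P_high", params),
      P2 = make_scenario_profile("reversed_polarized", params),
      zygote = make_scenario_profile("uniform_A_high", params))
  if (is.null(cue))
    cue <- switch(name,
      P1 = spatial_cue(0, L / 6, 0.1, 10, 75, mode = "attract"),
      P2 = spatial_cue(L, L / 6, 1, 10, 75, mode = "inhibit"),
      zygote = spatial_cue(0, L / 6, 0.1, 10, 75, mode = "attract"))
  structure(list(name = name, initial = initial, cue = cue),
            class = "scenario_spec")
}

#' Run a polarization scenario
#'
#' Integrates the PDE model from the scenario's initial profile with its cue
#' and the schedule in `params$kAP_schedule`, recording profiles and
#' diagnostics at a fixed cadence.
#'
#' @param spec a `scenario_spec`.
#' @param params a `pde_params` object.
#' @param t_end final time.
#' @param output_every output cadence (time units).
#' @return List with `frames` (list of `spatial_profile`) and `diagnostics`
#'   (data.frame: `time`, `asi_A`, `asi_P`, `n_domains_A`, `n_domains_P`,
#'   `class` — the coarse two-halves polarity class).
#' @export
run_scenario <- function(spec, params = pde_params(), t_end = 300,
                         output_every = 1) {
  p <- params
  prof <- spec$initial
  cue <- spec$cue
  x <- prof$x
  steps_per_frame <- max(1L, round(output_every / p$dt))
  n_frames <- ceiling(t_end / output_every)
  min_w <- max(2L, ceiling(0.05 * p$N))
  periodic <- p$boundary == "periodic"
  frames <- vector("list", n_frames + 1L)
  diag <- vector("list", n_frames + 1L)
  snap <- function(prof, t) {
    half <- p$N %/% 2
    coarse <- c(Aa = mean(prof$A[1:half]), Ap = mean(prof$A[(half + 1):p$N]),
                Pa = mean(prof$P[1:half]), Pp = mean(prof$P[(half + 1):p$N]))
    data.frame(time = t,
               asi_A = asi_of_profile(prof$A),
               asi_P = asi_of_profile(prof$P),
               n_domains_A = count_domains(prof$A, min_width = min_w,
                                           periodic = periodic),
               n_domains_P = count_domains(prof$P, min_width = min_w,
                                           periodic = periodic),
               class = classify_quadrant(coarse, dead_zone = 0.01))
  }
  frames[[1]] <- prof
  diag[[1]] <- snap(prof, 0)
  A <- prof$A; P <- prof$P
  w <- if (is.null(cue)) NULL else .cue_weights(cue, x)
  clip_warned <- FALSE
  for (fr in seq_len(n_frames)) {
    for (s in seq_len(steps_per_frame)) {
      t <- (fr - 1) * output_every + (s - 1) * p$dt
      m <- schedule_multiplier(p$kAP_schedule, t)
      Ac <- p$rhoA - p$psi * mean(A)
      Pc <- p$rhoP - p$psi * mean(P)
      r <- if (is.null(cue)) 0 else
        if (t >= cue$t_on && t <= cue$t_off) cue$rate else 0
      dA <- p$DA * .laplacian(A, p$dx, p$boundary) + p$konA * Ac -
        p$koffA * A - m * p$kAP * P^p$alpha * A
      if (!is.null(cue)) dA <- dA + .cue_term(cue, w, A, r)
      dP <- p$DP * .laplacian(P, p$dx, p$boundary) + p$konP * Pc -
        p$koffP * P - p$kPA * A^p$beta * P
      A <- A + p$dt * dA
      P <- P + p$dt * dP
      if (any(A < 0) || any(P < 0)) {
        if (!clip_warned) {
          warning("concentration clipped at zero during scenario run")
          clip_warned <- TRUE
        }
        A <- pmax(A, 0); P <- pmax(P, 0)
      }
    }
    prof <- spatial_profile(x, A, P)
    frames[[fr + 1]] <- prof
    diag[[fr + 1]] <- snap(prof, fr * output_every)
  }
  list(frames = frames, diagnostics = do.call(rbind, diag))
}
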