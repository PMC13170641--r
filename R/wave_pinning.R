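#' Parameters for the one-species wave-pinning polarity model
#'
#' A single polarity species `X` in two membrane compartments exchanging at
#' rate `Dtilde`, binding from a shared cytoplasmic pool with basal rate
#' `kon`, detaching at `koff`, and recruiting additional cytoplasmic protein
#' through saturating (Hill) positive feedback with strength `gamma` and
#' saturation constant `K`. Mass conservation acts through
#' `Xcyto = rhoX - psi * (Xa + Xp) / 2`.
#'
#' Defaults sit in the bistable regime: a mirror pair of polarized attractors
#' separated by an unstable symmetric state.
#'
#' @param Dtilde exchange rate (1/time).
#' @param kon basal attachment rate (1/time).
#' @param koff detachment rate (1/time).
#' @param gamma feedback strength (1/time).
#' @param K Hill saturation constant (a.u., > 0).
#' @param n Hill coefficient (>= 1).
#' @param rhoX total pool (a.u.).
#' @param psi surface-to-volume ratio (> 0).
#' @return An object of class `wavepin_params`.
#' @export
wavepin_params <- function(Dtilde = 0.05, kon = 0.067, koff = 1, gamma = 1.5,
                           K = 1, n = 2, rhoX = 2, psi = 1) {
  p <- list(Dtilde = Dtilde, kon = kon, koff = koff, gamma = gamma, K = K,
            n = n, rhoX = rhoX, psi = psi)
  if (any(unlist(p) < 0) || K <= 0 || psi <= 0 || n < 1)
    stop("invalid wave-pinning parameters")
  structure(p, class = "wavepin_params")
}

.coerce_wp <- function(x) .coerce_state(x, c("Xa", "Xp"))

.wp_rhs <- function(y, p, mult = 1, r = 0) {
  Xa <- y[[1]]; Xp <- y[[2]]
  Xc <- p$rhoX - p$psi * (Xa + Xp) / 2
  g <- mult * p$gamma
  c(p$Dtilde * (Xp - Xa) + p$kon * Xc - p$koff * Xa +
      g * Xc * Xa^p$n / (p$K^p$n + Xa^p$n) + r * Xp,
    p$Dtilde * (Xa - Xp) + p$kon * Xc - p$koff * Xp +
      g * Xc * Xp^p$n / (p$K^p$n + Xp^p$n) - r * Xp)
}

#' Right-hand side of the wave-pinning model
#'
#' Membrane detachment carries a negative sign (`-koff * X`): positive
#' feedback is the Hill recruitment term, and unbounded growth would
#' otherwise result.
#'
#' @param state named vector `c(Xa, Xp)`.
#' @param params a `wavepin_params` object.
#' @param multiplier feedback multiplier applied to `gamma`.
#' @param cue_rate instantaneous redistribution rate (Xp to Xa).
#' @return Named derivative vector `c(Xa, Xp)`.
#' @export
wavepin_rhs <- function(state, params, multiplier = 1, cue_rate = 0) {
  state <- .coerce_wp(state)
  Xc <- params$rhoX - params$psi * (state[["Xa"]] + state[["Xp"]]) / 2
  if (Xc < 0) stop("inadmissible pool: negative Xcyto")
  d <- .wp_rhs(as.numeric(state[c("Xa", "Xp")]), params, multiplier,
               cue_rate)
  names(d) <- c("Xa", "Xp")
  d
}

.wp_jacobian <- function(y, p, mult = 1, r = 0) {
  Xa <- y[[1]]; Xp <- y[[2]]
  Xc <- p$rhoX - p$psi * (Xa + Xp) / 2
  g <- mult * p$gamma
  hill <- function(x) x^p$n / (p$K^p$n + x^p$n)
  dhill <- function(x) p$n * x^(p$n - 1) * p$K^p$n / (p$K^p$n + x^p$n)^2
  dXc <- -p$psi / 2
  J <- matrix(0, 2, 2, dimnames = list(c("Xa", "Xp"), c("Xa", "Xp")))
  J[1, 1] <- -p$Dtilde + p$kon * dXc - p$koff +
    g * (dXc * hill(Xa) + Xc * dhill(Xa))
  J[1, 2] <- p$Dtilde + p$kon * dXc + g * dXc * hill(Xa) + r
  J[2, 1] <- p$Dtilde + p$kon * dXc + g * dXc * hill(Xp)
  J[2, 2] <- -p$Dtilde + p$kon * dXc - p$koff +
    g * (dXc * hill(Xp) + Xc * dhill(Xp)) - r
  J
}

#' Fixed points of the wave-pinning model
#'
#' Multi-start Newton iteration over a deterministic grid of `(Xa, Xp)`
#' initial states; duplicates merged; stability from the analytic Jacobian.
#' Symmetric (`Xa == Xp`) and polarized (asymmetric) fixed points are both
#' reported.
#'
#' @param params a `wavepin_params` object.
#' @param multiplier feedback multiplier on `gamma`.
#' @param grid_density grid values per dimension.
#' @param tol residual tolerance.
#' @param dedup_tol merge distance for duplicate roots.
#' @return A data.frame with `Xa`, `Xp`, `stability`, `max_eig_re`,
#'   `residual`.
#' @export
wavepin_fixed_points <- function(params, multiplier = 1, grid_density = 9,
                                 tol = 1e-9, dedup_tol = 1e-6) {
  hi <- 2 * params$rhoX / params$psi
  g <- seq(0, hi, length.out = grid_density)
  starts <- as.matrix(expand.grid(Xa = g, Xp = g))
  starts <- starts[params$rhoX - params$psi * rowSums(starts) / 2 >= 0, ,
                   drop = FALSE]
  roots <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(starts))) {
    y <- starts[i, ]
    f <- .wp_rhs(y, params, multiplier)
    ok <- FALSE
    for (it in 1:100) {
      if (max(abs(f)) < 1e-12) { ok <- TRUE; break }
      step <- tryCatch(solve(.wp_jacobian(y, params, multiplier), f),
                       error = function(e) NULL)
      if (is.null(step)) break
      lam <- 1
      repeat {
        y_new <- y - lam * step
        f_new <- .wp_rhs(y_new, params, multiplier)
        if (all(is.finite(f_new)) && max(abs(f_new)) <= max(abs(f))) break
        lam <- lam / 2
        if (lam < 1e-6) break
      }
      if (lam < 1e-6) break
      y <- y_new; f <- f_new
      if (any(abs(y) > 1e3)) break
    }
    if (!ok || any(y < -1e-8)) next
    y <- pmax(y, 0)
    if (max(abs(.wp_rhs(y, params, multiplier))) > tol) next
    if (nrow(roots) == 0 ||
        min(sqrt(colSums((t(roots) - y)^2))) > dedup_tol)
      roots <- rbind(roots, y)
  }
  if (nrow(roots) == 0)
    return(data.frame(Xa = numeric(0), Xp = numeric(0),
                      stability = character(0), max_eig_re = numeric(0),
                      residual = numeric(0)))
  out <- do.call(rbind, lapply(seq_len(nrow(roots)), function(i) {
    ev <- sort(Re(eigen(.wp_jacobian(roots[i, ], params, multiplier),
                        only.values = TRUE)$values), decreasing = TRUE)
    data.frame(Xa = roots[i, 1], Xp = roots[i, 2],
               stability = if (all(ev < -1e-8)) "stable"
                           else if (all(ev > 1e-8)) "unstable"
                           else "saddle",
               max_eig_re = ev[1],
               residual = max(abs(.wp_rhs(roots[i, ], params, multiplier))))
  }))
  out[order(out$Xa), , drop = FALSE]
}

#' Simulate the wave-pinning model
#'
#' As [simulate_ode()] but for the one-species model; the feedback schedule
#' multiplies `gamma` and the cue redistributes `X` from the posterior to the
#' anterior compartment.
#'
#' @param initial named vector `c(Xa, Xp)`.
#' @param params a `wavepin_params` object.
#' @param t_span output times.
#' @param schedule a `feedback_schedule` applied to `gamma`.
#' @param cue a `polarity_cue` or `NULL`.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `time`, `Xa`, `Xp`, `Xcyto`,
#'   `gamma_multiplier`, `cue_active`.
#' @export
wavepin_simulate <- function(initial, params, t_span,
                             schedule = constant_schedule(), cue = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  y0 <- as.numeric(.coerce_wp(initial))
  deriv <- function(t, y, parms)
    list(.wp_rhs(y, params, schedule_multiplier(schedule, t),
                 cue_rate(cue, t)))
  t0 <- t_span[1]; t1 <- t_span[length(t_span)]
  times <- sort(unique(c(t_span, .event_times(schedule, cue, t0, t1))))
  out <- deSolve::ode(y0, times, deriv, NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
  out <- out[match(t_span, out[, 1]), , drop = FALSE]
  Xc <- params$rhoX - params$psi * (out[, 2] + out[, 3]) / 2
  if (any(Xc < -1e-6)) stop("pool exhaustion during integration")
  data.frame(time = out[, 1], Xa = out[, 2], Xp = out[, 3], Xcyto = Xc,
             gamma_multiplier = schedule_multiplier(schedule, out[, 1]),
             cue_active = cue_rate(cue, out[, 1]) > 0)
}
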