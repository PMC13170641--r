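#' Parameters for the two-compartment PAR model
#'
#' Rate constants, pools and antagonism exponents for the four-ODE PAR model
#' in which anterior and posterior membrane compartments exchange protein at
#' rate `Dtilde`, bind from and unbind to shared cytoplasmic pools, and
#' mutually antagonize each other (`kAP`: pPAR removes aPAR; `kPA`: aPAR
#' removes pPAR).
#'
#' @param Dtilde inter-compartment exchange rate (1/time).
#' @param kon membrane attachment rate (1/time).
#' @param koff membrane detachment rate (1/time).
#' @param kAP P-to-A antagonism coefficient (conc^-alpha/time).
#' @param kPA A-to-P antagonism coefficient (conc^-beta/time).
#' @param alpha,beta antagonism exponents (integers >= 1).
#' @param rhoA,rhoP total aPAR and pPAR pools (a.u.).
#' @param psi surface-to-volume ratio (> 0).
#' @return An object of class `ode_params`.
#' @seealso [par_regime()] for the shipped named parameter sets.
#' @export
ode_params <- function(Dtilde = 0.1, kon = 1, koff = 0.3, kAP = 50, kPA = 50,
                       alpha = 2, beta = 2, rhoA = 1, rhoP = 1, psi = 1) {
  p <- list(Dtilde = Dtilde, kon = kon, koff = koff, kAP = kAP, kPA = kPA,
            alpha = alpha, beta = beta, rhoA = rhoA, rhoP = rhoP, psi = psi)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 ||
                   !is.finite(x), logical(1))))
    stop("all parameters must be finite scalars")
  if (any(unlist(p[c("Dtilde", "kon", "koff", "kAP", "kPA",
                     "rhoA", "rhoP")]) < 0))
    stop("rates and pools must be >= 0")
  if (p$psi <= 0) stop("psi must be > 0")
  if (p$alpha < 1 || p$beta < 1) stop("antagonism exponents must be >= 1")
  structure(p, class = "ode_params")
}

#' Named default parameter sets
#'
#' `"high_feedback"` sits in the multistable regime with four stable polarity
#' attractors (two uniform, two polarized) plus a central unstable point;
#' `"low_feedback"` reduces P-to-A antagonism so that only the single uniform
#' aPAR-high state survives. Both sets are calibrated to this qualitative
#' regime structure (see the package vignette).
#'
#' @param name `"high_feedback"` or `"low_feedback"`.
#' @return An `ode_params` object.
#' @export
par_regime <- function(name = c("high_feedback", "low_feedback")) {
  name <- match.arg(name)
  if (name == "high_feedback") ode_params() else ode_params(kAP = 0.5)
}

#' Default low-feedback multiplier
#'
#' The kAP multiplier that maps the high-feedback set onto the low-feedback
#' set (`0.5 / 50`), used for the constant-low regime and the low phase of the
#' oscillating schedule.
#' @return A scalar multiplier.
#' @export
low_feedback_multiplier <- function() 0.01

.state_names <- c("Aa", "Ap", "Pa", "Pp")

## tolerant state coercion: exact names win, otherwise positional order
.coerce_state <- function(x, nms = .state_names) {
  if (!is.null(names(x)) && all(nms %in% names(x)))
    v <- as.numeric(x[nms])
  else if (length(x) == length(nms))
    v <- as.numeric(x)
  else stop("state must have components ", paste(nms, collapse = ", "))
  if (any(!is.finite(v))) stop("state contains non-finite values")
  stats::setNames(v, nms)
}

#' Construct a compartment state
#'
#' @param Aa,Ap membrane aPAR concentration in the anterior / posterior
#'   compartment (a.u.).
#' @param Pa,Pp membrane pPAR concentration in the anterior / posterior
#'   compartment (a.u.).
#' @return A named numeric vector `c(Aa, Ap, Pa, Pp)`.
#' @export
compartment_state <- function(Aa, Ap, Pa, Pp) {
  s <- c(Aa = Aa, Ap = Ap, Pa = Pa, Pp = Pp)
  if (any(!is.finite(s)) || any(s < 0))
    stop("compartment concentrations must be finite and >= 0")
  s
}

#' Cytoplasmic pools implied by a membrane state
#'
#' Mass conservation ties the cytoplasmic concentrations to the membrane
#' state: `Acyto = rhoA - psi * (Aa + Ap) / 2`, and analogously for pPAR.
#'
#' @param state named state vector (see [compartment_state()]).
#' @param params an `ode_params` object.
#' @return Named vector `c(Acyto, Pcyto)`.
#' @export
cytoplasmic_pools <- function(state, params) {
  state <- .coerce_state(state)
  Acyto <- params$rhoA - params$psi * (state[["Aa"]] + state[["Ap"]]) / 2
  Pcyto <- params$rhoP - params$psi * (state[["Pa"]] + state[["Pp"]]) / 2
  if (Acyto < 0 || Pcyto < 0)
    stop("inadmissible parameters/state: negative cytoplasmic pool")
  c(Acyto = Acyto, Pcyto = Pcyto)
}

## core rhs on raw numbers; mult scales kAP (and kPA if co-oscillating),
## r is the instantaneous cue redistribution rate
.par_rhs <- function(y, p, mult = 1, multP = 1, r = 0) {
  Aa <- y[[1]]; Ap <- y[[2]]; Pa <- y[[3]]; Pp <- y[[4]]
  Ac <- p$rhoA - p$psi * (Aa + Ap) / 2
  Pc <- p$rhoP - p$psi * (Pa + Pp) / 2
  kAP <- mult * p$kAP
  kPA <- multP * p$kPA
  c(p$Dtilde * (Ap - Aa) + p$kon * Ac - p$koff * Aa - kAP * Pa^p$alpha * Aa + r * Ap,
    p$Dtilde * (Aa - Ap) + p$kon * Ac - p$koff * Ap - kAP * Pp^p$alpha * Ap - r * Ap,
    p$Dtilde * (Pp - Pa) + p$kon * Pc - p$koff * Pa - kPA * Aa^p$beta * Pa,
    p$Dtilde * (Pa - Pp) + p$kon * Pc - p$koff * Pp - kPA * Ap^p$beta * Pp)
}

#' Right-hand side of the four-ODE PAR model
#'
#' Time derivatives of the four membrane concentrations under exchange,
#' attachment from the (mass-conserving) cytoplasmic pools, detachment,
#' mutual antagonism with feedback scaled by the schedule, and the
#' redistribution cue.
#'
#' @param state named state vector.
#' @param t time.
#' @param params an `ode_params` object.
#' @param schedule a `feedback_schedule` (default: constant 1).
#' @param cue a `polarity_cue` or `NULL`.
#' @return Named vector of derivatives `c(Aa, Ap, Pa, Pp)`.
#' @export
ode_rhs <- function(state, t = 0, params, schedule = NULL, cue = NULL) {
  state <- .coerce_state(state)
  cytoplasmic_pools(state, params)  # errors on inadmissible pools
  m <- if (is.null(schedule)) 1 else schedule_multiplier(schedule, t)
  mP <- if (!is.null(schedule) && schedule$apply_to_kPA) m else 1
  d <- .par_rhs(as.numeric(state[.state_names]), params, m, mP,
                cue_rate(cue, t))
  names(d) <- .state_names
  d
}

#' Analytic Jacobian of the PAR right-hand side
#'
#' @inheritParams ode_rhs
#' @param multiplier kAP multiplier (scalar).
#' @param multiplier_kPA kPA multiplier (scalar).
#' @param cue_rate instantaneous cue rate (scalar).
#' @return 4x4 Jacobian matrix (rows/cols ordered Aa, Ap, Pa, Pp).
#' @export
ode_jacobian <- function(state, params, multiplier = 1, multiplier_kPA = 1,
                         cue_rate = 0) {
  state <- .coerce_state(state)
  p <- params
  Aa <- state[["Aa"]]; Ap <- state[["Ap"]]
  Pa <- state[["Pa"]]; Pp <- state[["Pp"]]
  kAP <- multiplier * p$kAP
  kPA <- multiplier_kPA * p$kPA
  kp2 <- -p$kon * p$psi / 2  # d(kon*Acyto)/dAa = d/dAp
  a <- p$alpha; b <- p$beta
  J <- matrix(0, 4, 4, dimnames = list(.state_names, .state_names))
  J["Aa", ] <- c(-p$Dtilde + kp2 - p$koff - kAP * Pa^a,
                 p$Dtilde + kp2 + cue_rate,
                 -kAP * a * Pa^(a - 1) * Aa, 0)
  J["Ap", ] <- c(p$Dtilde + kp2,
                 -p$Dtilde + kp2 - p$koff - kAP * Pp^a - cue_rate,
                 0, -kAP * a * Pp^(a - 1) * Ap)
  J["Pa", ] <- c(-kPA * b * Aa^(b - 1) * Pa, 0,
                 -p$Dtilde + kp2 - p$koff - kPA * Aa^b,
                 p$Dtilde + kp2)
  J["Pp", ] <- c(0, -kPA * b * Ap^(b - 1) * Pp,
                 p$Dtilde + kp2,
                 -p$Dtilde + kp2 - p$koff - kPA * Ap^b)
  J
}

#' Simulate the two-compartment PAR model
#'
#' Integrates the four-ODE model with a stiff-capable solver (lsoda).
#' Integration is segmented at schedule breakpoints and cue on/off times so
#' that the solver never steps across a non-smooth point.
#'
#' @param initial named initial state (see [compartment_state()]).
#' @param params an `ode_params` object.
#' @param t_span numeric vector of output times (increasing, >= 2 values).
#' @param schedule a `feedback_schedule` (default constant 1).
#' @param cue a `polarity_cue` or `NULL`.
#' @param rtol,atol solver tolerances.
#' @return A data.frame with columns `time`, `Aa`, `Ap`, `Pa`, `Pp`,
#'   `Acyto`, `Pcyto`, `kAP_multiplier`, `cue_active`.
#' @export
simulate_ode <- function(initial, params, t_span,
                         schedule = constant_schedule(), cue = NULL,
                         rtol = 1e-8, atol = 1e-10) {
  stopifnot(length(t_span) >= 2, !is.unsorted(t_span))
  initial <- .coerce_state(initial)
  cytoplasmic_pools(initial, params)
  y0 <- as.numeric(initial)
  deriv <- function(t, y, parms) {
    m <- schedule_multiplier(schedule, t)
    mP <- if (schedule$apply_to_kPA) m else 1
    list(.par_rhs(y, params, m, mP, cue_rate(cue, t)))
  }
  t0 <- t_span[1]; t1 <- t_span[length(t_span)]
  breaks <- .event_times(schedule, cue, t0, t1)
  times <- sort(unique(c(t_span, breaks)))
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE integration failed")
  out <- out[match(t_span, out[, 1]), , drop = FALSE]
  states <- out[, 2:5, drop = FALSE]
  colnames(states) <- .state_names
  Acyto <- params$rhoA - params$psi * (states[, "Aa"] + states[, "Ap"]) / 2
  Pcyto <- params$rhoP - params$psi * (states[, "Pa"] + states[, "Pp"]) / 2
  if (any(Acyto < -1e-6) || any(Pcyto < -1e-6))
    stop("pool exhaustion during integration")
  data.frame(time = out[, 1], states,
             Acyto = Acyto, Pcyto = Pcyto,
             kAP_multiplier = schedule_multiplier(schedule, out[, 1]),
             cue_active = cue_rate(cue, out[, 1]) > 0)
}

## damped Newton on the fixed-feedback rhs; returns root or NULL
.newton_root <- function(y0, params, mult, multP, r, tol = 1e-11,
                         max_iter = 200) {
  y <- y0
  f <- .par_rhs(y, params, mult, multP, r)
  for (i in seq_len(max_iter)) {
    if (max(abs(f)) < tol) return(y)
    st <- stats::setNames(y, .state_names)
    J <- ode_jacobian(st, params, mult, multP, r)
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    lam <- 1
    repeat {
      y_new <- y - lam * step
      f_new <- .par_rhs(y_new, params, mult, multP, r)
      if (all(is.finite(f_new)) &&
          max(abs(f_new)) < max(abs(f)) * (1 - 0.25 * lam) + tol) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    y <- y_new; f <- f_new
    if (any(abs(y) > 1e3)) return(NULL)
  }
  if (max(abs(f)) < tol) y else NULL
}

#' Classify the stability of a fixed point
#'
#' Linearizes the right-hand side at the candidate fixed point using the
#' analytic Jacobian and inspects the real parts of its eigenvalues.
#'
#' @param state named state vector (a root of the rhs within tolerance).
#' @param params an `ode_params` object.
#' @param multiplier kAP multiplier held fixed.
#' @param multiplier_kPA kPA multiplier held fixed.
#' @param cue_rate fixed cue rate.
#' @param tol_eig eigenvalues within `tol_eig` of zero trigger a
#'   degenerate-eigenvalue warning.
#' @return A list with `label` (`"stable"`, `"unstable"` or `"saddle"`) and
#'   `eigenvalues` (real parts, decreasing).
#' @export
classify_stability <- function(state, params, multiplier = 1,
                               multiplier_kPA = 1, cue_rate = 0,
                               tol_eig = 1e-8) {
  J <- ode_jacobian(state, params, multiplier, multiplier_kPA, cue_rate)
  re <- sort(Re(eigen(J, only.values = TRUE)$values), decreasing = TRUE)
  if (any(abs(re) < tol_eig))
    warning("degenerate eigenvalue: |Re| below tolerance")
  label <- if (all(re < -tol_eig)) "stable"
           else if (all(re > tol_eig)) "unstable"
           else "saddle"
  list(label = label, eigenvalues = re)
}

#' Enumerate steady states of the PAR model
#'
#' Multi-start damped Newton iteration from a deterministic grid of initial
#' states spanning the admissible region, with duplicate roots merged and
#' stability classified from the analytic Jacobian. Feedback multiplier and
#' cue rate are held constant (the autonomous system).
#'
#' @param params an `ode_params` object.
#' @param multiplier kAP multiplier.
#' @param multiplier_kPA kPA multiplier.
#' @param cue_rate constant cue rate.
#' @param grid_density number of grid values per state dimension.
#' @param tol residual tolerance `max |rhs|` for accepting a root.
#' @param dedup_tol Euclidean merge distance for duplicate roots.
#' @return A data.frame with columns `Aa`, `Ap`, `Pa`, `Pp`, `stability`,
#'   `max_eig_re`, `residual`, one row per distinct fixed point.
#' @export
find_steady_states <- function(params, multiplier = 1, multiplier_kPA = 1,
                               cue_rate = 0, grid_density = 5, tol = 1e-9,
                               dedup_tol = 1e-6) {
  hi <- 2 * max(params$rhoA, params$rhoP) / params$psi
  g <- seq(0, hi, length.out = grid_density)
  starts <- as.matrix(expand.grid(Aa = g, Ap = g, Pa = g, Pp = g))
  adm <- (params$rhoA - params$psi * (starts[, 1] + starts[, 2]) / 2 >= 0) &
         (params$rhoP - params$psi * (starts[, 3] + starts[, 4]) / 2 >= 0)
  starts <- starts[adm, , drop = FALSE]
  roots <- matrix(numeric(0), ncol = 4)
  for (i in seq_len(nrow(starts))) {
    r <- .newton_root(starts[i, ], params, multiplier, multiplier_kPA,
                      cue_rate, tol = min(tol, 1e-11))
    if (is.null(r) || any(r < -1e-8)) next
    r <- pmax(r, 0)
    if (max(abs(.par_rhs(r, params, multiplier, multiplier_kPA,
                         cue_rate))) > tol) next
    if (nrow(roots) == 0 ||
        min(sqrt(colSums((t(roots) - r)^2))) > dedup_tol)
      roots <- rbind(roots, r)
  }
  if (nrow(roots) == 0)
    return(data.frame(Aa = numeric(0), Ap = numeric(0), Pa = numeric(0),
                      Pp = numeric(0), stability = character(0),
                      max_eig_re = numeric(0), residual = numeric(0)))
  info <- lapply(seq_len(nrow(roots)), function(i) {
    st <- stats::setNames(roots[i, ], .state_names)
    cl <- suppressWarnings(
      classify_stability(st, params, multiplier, multiplier_kPA, cue_rate))
    data.frame(Aa = st[["Aa"]], Ap = st[["Ap"]], Pa = st[["Pa"]],
               Pp = st[["Pp"]], stability = cl$label,
               max_eig_re = cl$eigenvalues[1],
               residual = max(abs(.par_rhs(roots[i, ], params, multiplier,
                                           multiplier_kPA, cue_rate))))
  })
  out <- do.call(rbind, info)
  out[order(-out$Aa + out$Pa), , drop = FALSE]
}

#' Classify a state into a polarity quadrant
#'
#' The landscape coordinates are the concentration differences between aPAR
#' and pPAR in each compartment. The label follows the sign pattern of
#' `(Aa - Pa, Ap - Pp)`; states with either difference inside the dead zone
#' are `UNDEFINED`.
#'
#' @param state named state vector.
#' @param dead_zone threshold below which a difference counts as zero;
#'   default 1% of the no-feedback uniform balance `max(rhoA, rhoP) * kon /
#'   (koff + kon * psi)` when `params` is given, else 0.01.
#' @param params optional `ode_params` used for the default dead zone.
#' @return One of `"UNIFORM_A"`, `"UNIFORM_P"`, `"POLARIZED_AP"`,
#'   `"POLARIZED_PA"`, `"UNDEFINED"`.
#' @export
classify_quadrant <- function(state, dead_zone = NULL, params = NULL) {
  if (is.null(dead_zone)) {
    dead_zone <- if (is.null(params)) 0.01 else
      0.01 * max(params$rhoA, params$rhoP) * params$kon /
        (params$koff + params$kon * params$psi)
  }
  state <- .coerce_state(state)
  da <- state[["Aa"]] - state[["Pa"]]
  dp <- state[["Ap"]] - state[["Pp"]]
  if (abs(da) <= dead_zone || abs(dp) <= dead_zone) return("UNDEFINED")
  if (da > 0 && dp > 0) "UNIFORM_A"
  else if (da < 0 && dp < 0) "UNIFORM_P"
  else if (da > 0) "POLARIZED_AP"
  else "POLARIZED_PA"
}

#' Cue-induced state switching across feedback regimes
#'
#' Reproduces the state-switching experiment: each stable attractor of the
#' high-feedback model is used as an initial condition and exposed to a
#' transient cue under three feedback regimes — constant high, constant low,
#' and oscillating (low during the cue window, rising to high as the cue
#' ends). After cue withdrawal the system relaxes under its terminal regime
#' and the final state is classified.
#'
#' @param params an `ode_params` object (the high-feedback set).
#' @param cue a `polarity_cue`; the default (rate 0.5 on `[10, 75]`) overlaps
#'   the rise of the default oscillating schedule.
#' @param schedule_osc oscillating `feedback_schedule`.
#' @param multiplier_low multiplier for the constant-low regime.
#' @param t_end final time (well past cue withdrawal).
#' @param regimes subset of `c("constant_high", "constant_low", "oscillating")`.
#' @return A data.frame with columns `regime`, `initial`, `final`, plus the
#'   final state coordinates.
#' @export
run_switching_matrix <- function(params = par_regime("high_feedback"),
                                 cue = polarity_cue(0.5, 10, 75),
                                 schedule_osc = oscillating_schedule(),
                                 multiplier_low = low_feedback_multiplier(),
                                 t_end = 300,
                                 regimes = c("constant_high", "constant_low",
                                             "oscillating")) {
  fps <- find_steady_states(params)
  stable <- fps[fps$stability == "stable", , drop = FALSE]
  labels <- apply(stable[, .state_names], 1, classify_quadrant,
                  params = params)
  schedules <- list(constant_high = constant_schedule(1),
                    constant_low = constant_schedule(multiplier_low),
                    oscillating = schedule_osc)
  rows <- list()
  for (reg in regimes) {
    for (i in seq_len(nrow(stable))) {
      y0 <- stats::setNames(as.numeric(stable[i, .state_names]),
                            .state_names)
      tr <- simulate_ode(y0, params, c(0, t_end / 2, t_end),
                         schedule = schedules[[reg]], cue = cue)
      yf <- stats::setNames(as.numeric(tr[nrow(tr), .state_names]),
                            .state_names)
      rows[[length(rows) + 1]] <- data.frame(
        regime = reg, initial = labels[i],
        final = classify_quadrant(yf, params = params),
        Aa = yf[["Aa"]], Ap = yf[["Ap"]], Pa = yf[["Pa"]], Pp = yf[["Pp"]])
    }
  }
  do.call(rbind, rows)
}
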