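# shared fixtures: small, fast model/imaging configurations used across tests

high_fb <- function() par_regime("high_feedback")
low_fb <- function() par_regime("low_feedback")

# no-feedback linear model: attachment/detachment balance is analytic
linear_params <- function() ode_params(kAP = 0, kPA = 0)

linear_balance <- function(p, rho) p$kon * rho / (p$koff + p$kon * p$psi)

# small synthetic embryo (fast to render and quantify)
small_embryo <- function(amplitude = 1, noise_sd = 0, seed = 1, ...) {
  embryo_truth(semi_axes_um = c(8, 5), amplitude = amplitude, cyto = 0.4,
               bg = 0.1, membrane_sigma_px = 3, noise_sd = noise_sd,
               margin_px = 60, seed = seed, ...)
}

# coarse PDE model for unit tests (scenario tests use the full N = 128)
small_pde <- function(...) pde_params(N = 32, L = 60, ...)

expect_state_equal <- function(a, b, tol = 1e-6) {
  expect_equal(as.numeric(a[c("Aa", "Ap", "Pa", "Pp")]),
               as.numeric(b[c("Aa", "Ap", "Pa", "Pp")]), tolerance = tol)
}
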