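test_that("a uniform no-feedback balance profile is a fixed point of pde_step", {
  p <- small_pde(kAP = 0, kPA = 0)
  balA <- p$konA * p$rhoA / (p$koffA + p$konA * p$psi)
  balP <- p$konP * p$rhoP / (p$koffP + p$konP * p$psi)
  prof <- spatial_profile(pde_grid(p), rep(balA, p$N), rep(balP, p$N))
  out <- pde_step(prof, p, 0)
  expect_equal(out$A, prof$A, tolerance = 1e-12)
  expect_equal(out$P, prof$P, tolerance = 1e-12)
})

test_that("transport and cue terms move mass without creating it", {
  p <- small_pde()
  set.seed(2)
  u <- runif(p$N, 0, 1)
  # discrete diffusion conserves the membrane sum under both boundary rules
  expect_equal(sum(parosc:::.laplacian(u, p$dx, "no_flux")), 0,
               tolerance = 1e-10)
  expect_equal(sum(parosc:::.laplacian(u, p$dx, "periodic")), 0,
               tolerance = 1e-10)
  # the attract-mode cue is a pure membrane redistribution: sums to zero
  cue_a <- spatial_cue(0, 10, 0.5, 0, 50, mode = "attract")
  w <- parosc:::.cue_weights(cue_a, pde_grid(p))
  expect_equal(sum(parosc:::.cue_term(cue_a, w, u, 0.5)), 0,
               tolerance = 1e-12)
  # the inhibit-mode cue only removes membrane protein (to the pool)
  cue_i <- spatial_cue(p$L, 10, 1, 0, 50, mode = "inhibit")
  wi <- parosc:::.cue_weights(cue_i, pde_grid(p))
  expect_true(all(parosc:::.cue_term(cue_i, wi, u, 1) <= 0))
  # pools stay admissible through a scenario burst
  pp <- small_pde(kAP_schedule = oscillating_schedule())
  prof <- make_scenario_profile("reversed_polarized", pp)
  for (k in 1:200) {
    prof <- pde_step(prof, pp, t = (k - 1) * pp$dt, cue = cue_i)
    expect_gte(pp$rhoA - pp$psi * mean(prof$A), -1e-12)
    expect_gte(pp$rhoP - pp$psi * mean(prof$P), -1e-12)
  }
})

test_that("halving dt shows first-order temporal self-convergence", {
  run_dt <- function(dt) {
    # moderate feedback keeps the reaction terms well inside the explicit
    # stability region at the coarsest step, so the clean O(dt) error shows
    p <- pde_params(N = 32, L = 60, dt = dt, kAP = 5, kPA = 5,
                    kAP_schedule = constant_schedule())
    prof <- make_scenario_profile("reversed_polarized", p)
    n <- round(5 / dt)
    for (k in seq_len(n)) prof <- pde_step(prof, p, t = (k - 1) * dt)
    c(prof$A, prof$P)
  }
  u1 <- run_dt(0.02)
  u2 <- run_dt(0.01)
  u3 <- run_dt(0.005)
  e12 <- max(abs(u1 - u2))
  e23 <- max(abs(u2 - u3))
  expect_gt(e12 / e23, 1.7)  # ~2 for first order
  expect_lt(e12 / e23, 2.4)
})

test_that("with two boxes the PDE reduces to the compartment ODE model", {
  # D / dx^2 with N = 2 equals the inter-compartment exchange rate Dtilde
  L <- 2; D <- 0.1 * (L / 2)^2
  p2 <- pde_params(DA = D, DP = D, N = 2, L = L, dt = 0.001,
                   koffA = 0.3, koffP = 0.3)
  po <- ode_params(Dtilde = 0.1)
  prof <- spatial_profile(pde_grid(p2), c(0.8, 0.2), c(0.1, 0.6))
  nstep <- 2000  # t = 2
  for (k in seq_len(nstep)) prof <- pde_step(prof, p2, t = (k - 1) * p2$dt)
  ref <- simulate_ode(c(Aa = 0.8, Ap = 0.2, Pa = 0.1, Pp = 0.6), po, c(0, 2))
  expect_equal(c(prof$A, prof$P),
               as.numeric(ref[2, c("Aa", "Ap", "Pa", "Pp")]),
               tolerance = 2e-3)
})

test_that("very fast diffusion homogenizes to the well-mixed balance", {
  p <- pde_params(DA = 200, DP = 200, N = 16, L = 60, dt = 0.01,
                  kAP = 0, kPA = 0)
  prof <- spatial_profile(pde_grid(p), seq(0, 1, length.out = 16),
                          seq(1, 0, length.out = 16))
  for (k in seq_len(5000)) prof <- pde_step(prof, p, t = (k - 1) * p$dt)
  balA <- p$konA * p$rhoA / (p$koffA + p$konA * p$psi)
  expect_equal(prof$A, rep(balA, 16), tolerance = 1e-5)
  expect_lt(diff(range(prof$P)), 1e-5)
})

test_that("count_domains counts plateaus with width and wrap rules", {
  expect_equal(count_domains(rep(0.1, 50), threshold = 0.5), 0L)
  v <- rep(0, 50); v[10:20] <- 1
  expect_equal(count_domains(v, threshold = 0.5), 1L)
  v[35:42] <- 1
  expect_equal(count_domains(v, threshold = 0.5), 2L)
  # min_width suppresses slivers
  v2 <- rep(0, 50); v2[5] <- 1; v2[20:30] <- 1
  expect_equal(count_domains(v2, threshold = 0.5, min_width = 3), 1L)
  # periodic wrap merges end runs
  v3 <- rep(0, 50); v3[1:5] <- 1; v3[46:50] <- 1
  expect_equal(count_domains(v3, threshold = 0.5, periodic = TRUE), 1L)
  expect_equal(count_domains(v3, threshold = 0.5, periodic = FALSE), 2L)
  # default threshold is half the profile maximum
  v4 <- c(rep(0.4, 10), rep(1, 10), rep(0.4, 10))
  expect_equal(count_domains(v4), 1L)
})

test_that("asi_of_profile implements the printed formula", {
  expect_equal(asi_of_profile(rep(1, 40)), 0)
  expect_equal(asi_of_profile(c(rep(1, 20), rep(0, 20))), 0.5)
  expect_equal(asi_of_profile(c(rep(0, 20), rep(1, 20))), -0.5)
  # anterior sum 1, posterior sum 3 -> -0.25
  expect_equal(asi_of_profile(c(rep(0.1, 10), rep(0.3, 10))), -0.25)
  expect_error(asi_of_profile(rep(0, 10)), "undefined|A \\+ P")
})

test_that("kap_schedule_from_trace rescales traces into multipliers", {
  # constant trace: constant multiplier 1
  s1 <- kap_schedule_from_trace(c(0, 5, 10), c(2, 2, 2))
  expect_equal(schedule_multiplier(s1, c(0, 7)), c(1, 1))
  # two-point trace: exact linear interpolation between floor and 1
  s2 <- kap_schedule_from_trace(c(0, 10), c(0, 4), floor = 0.2)
  expect_equal(schedule_multiplier(s2, 5), 0.6)
  # synthetic oscillation trace: schedule low before condensation, peaks at
  # NEBD, drops after anaphase, matching the generator's phase marks
  tr <- oscillation_truth(noise_sd = 0)
  osc <- make_oscillation_trace(tr, dt = 0.05)
  sch <- kap_schedule_from_trace(osc$times, osc$levels, floor = 0.01)
  m <- schedule_multiplier(sch, osc$times)
  expect_equal(osc$times[which.max(m)], osc$phase_marks$t_nebd[1])
  expect_equal(max(m), 1)
  expect_equal(schedule_multiplier(sch, 0), 0.01, tolerance = 1e-9)
  expect_lt(schedule_multiplier(sch, tr$t_anaphase + tr$fall_time + 1), 0.05)
  expect_error(kap_schedule_from_trace(numeric(0), numeric(0)), "empty")
})

test_that("P1 polarizes under the oscillating schedule and locks under constant high feedback", {
  p_osc <- pde_params(kAP_schedule = oscillating_schedule())
  p_hi <- pde_params()
  r_osc <- run_scenario(scenario_spec("P1", p_osc), p_osc, t_end = 200)
  d <- r_osc$diagnostics
  expect_equal(d$class[nrow(d)], "POLARIZED_AP")
  expect_gt(d$asi_A[nrow(d)], 0.3)
  r_hi <- run_scenario(scenario_spec("P1", p_hi), p_hi, t_end = 200)
  d2 <- r_hi$diagnostics
  final <- r_hi$frames[[length(r_hi$frames)]]
  expect_false(d2$class[nrow(d2)] == "POLARIZED_AP")
  # aPAR membrane loading suppressed: mean far below the pPAR level
  expect_lt(mean(final$A), 0.2 * mean(final$P))
})

test_that("P2 shows the transient two-domain failure only under constant high feedback", {
  p_osc <- pde_params(kAP_schedule = oscillating_schedule())
  p_hi <- pde_params()
  r_hi <- run_scenario(scenario_spec("P2", p_hi), p_hi, t_end = 300)
  r_osc <- run_scenario(scenario_spec("P2", p_osc), p_osc, t_end = 300)
  expect_equal(r_hi$diagnostics$class[1], "POLARIZED_PA")  # reversed initial
  expect_gte(max(r_hi$diagnostics$n_domains_P), 2)
  after_transient <- r_osc$diagnostics$time > 5
  expect_lte(max(r_osc$diagnostics$n_domains_P[after_transient]), 1)
  expect_equal(r_osc$diagnostics$class[nrow(r_osc$diagnostics)],
               "POLARIZED_AP")
})
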