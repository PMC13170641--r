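test_that("cytoplasmic pools follow the conservation formula", {
  p <- high_fb()
  # empty membrane: pools equal the totals
  expect_equal(cytoplasmic_pools(compartment_state(0, 0, 0, 0), p),
               c(Acyto = p$rhoA, Pcyto = p$rhoP))
  # pool exhaustion boundary
  ex <- 2 * p$rhoA / p$psi
  expect_equal(cytoplasmic_pools(c(Aa = ex / 2, Ap = ex / 2, Pa = 0, Pp = 0),
                                 p)[["Acyto"]], 0)
  # generic: term-by-term arithmetic
  p2 <- ode_params(rhoA = 2, rhoP = 1.5, psi = 0.7)
  st <- c(Aa = 0.3, Ap = 0.9, Pa = 0.2, Pp = 0.4)
  expect_equal(cytoplasmic_pools(st, p2),
               c(Acyto = 2 - 0.7 * (0.3 + 0.9) / 2,
                 Pcyto = 1.5 - 0.7 * (0.2 + 0.4) / 2))
  # inadmissible state errors rather than returning a negative pool
  expect_error(cytoplasmic_pools(c(Aa = 3, Ap = 3, Pa = 0, Pp = 0), p),
               "inadmissible")
})

test_that("the rhs matches hand evaluation in its limiting and generic cases", {
  p <- high_fb()
  # empty membrane: only attachment acts
  d0 <- ode_rhs(compartment_state(0, 0, 0, 0), 0, p)
  expect_equal(unname(d0), c(p$kon * p$rhoA, p$kon * p$rhoA,
                             p$kon * p$rhoP, p$kon * p$rhoP))
  # symmetric state: exchange vanishes, dAa == dAp
  ds <- ode_rhs(c(Aa = 0.4, Ap = 0.4, Pa = 0.1, Pp = 0.1), 0, p)
  expect_equal(ds[["Aa"]], ds[["Ap"]])
  expect_equal(ds[["Pa"]], ds[["Pp"]])
  # schedule multiplier 0.5 equals an independent evaluation with kAP halved
  sch <- feedback_schedule(c(0, 10), c(0.5, 0.5))
  st <- c(Aa = 0.5, Ap = 0.3, Pa = 0.25, Pp = 0.45)
  got <- ode_rhs(st, 5, p, schedule = sch)
  ph <- ode_params(kAP = p$kAP * 0.5)
  expect_equal(got, ode_rhs(st, 5, ph))
})

test_that("the analytic Jacobian matches central finite differences", {
  p <- high_fb()
  st <- c(Aa = 0.52, Ap = 0.31, Pa = 0.27, Pp = 0.44)
  J <- ode_jacobian(st, p, multiplier = 0.6, cue_rate = 0.2)
  h <- 1e-6
  for (k in 1:4) {
    e <- numeric(4); e[k] <- h
    fp <- parosc:::.par_rhs(as.numeric(st) + e, p, 0.6, 1, 0.2)
    fm <- parosc:::.par_rhs(as.numeric(st) - e, p, 0.6, 1, 0.2)
    expect_equal(unname(J[, k]), (fp - fm) / (2 * h), tolerance = 1e-5)
  }
})

test_that("with no feedback the system relaxes to the analytic balance", {
  p <- linear_params()
  tr <- simulate_ode(c(Aa = 0.9, Ap = 0.1, Pa = 0.7, Pp = 0), p, c(0, 500))
  A_star <- linear_balance(p, p$rhoA)
  P_star <- linear_balance(p, p$rhoP)
  final <- as.numeric(tr[nrow(tr), c("Aa", "Ap", "Pa", "Pp")])
  expect_equal(final, c(A_star, A_star, P_star, P_star), tolerance = 1e-7)
})

test_that("mass is conserved and states stay nonnegative along trajectories", {
  p <- high_fb()
  cue <- polarity_cue(0.5, 10, 75)
  tr <- simulate_ode(c(Aa = 0.73, Ap = 0.73, Pa = 0.04, Pp = 0.04), p,
                     seq(0, 200, by = 10),
                     schedule = oscillating_schedule(), cue = cue)
  rhoA_t <- tr$Acyto + p$psi * (tr$Aa + tr$Ap) / 2
  rhoP_t <- tr$Pcyto + p$psi * (tr$Pa + tr$Pp) / 2
  expect_equal(rhoA_t, rep(p$rhoA, nrow(tr)), tolerance = 1e-9)
  expect_equal(rhoP_t, rep(p$rhoP, nrow(tr)), tolerance = 1e-9)
  expect_true(all(as.matrix(tr[, c("Aa", "Ap", "Pa", "Pp")]) > -1e-8))
})

test_that("fully symmetric parameters give swap-symmetric trajectories", {
  p <- high_fb()  # symmetric by construction
  y0 <- c(Aa = 0.8, Ap = 0.2, Pa = 0.1, Pp = 0.6)
  y0_swapped <- c(Aa = y0[["Pp"]], Ap = y0[["Pa"]],
                  Pa = y0[["Ap"]], Pp = y0[["Aa"]])
  ts <- seq(0, 50, by = 10)
  tr <- simulate_ode(y0, p, ts)
  trs <- simulate_ode(y0_swapped, p, ts)
  expect_equal(tr$Aa, trs$Pp, tolerance = 1e-7)
  expect_equal(tr$Ap, trs$Pa, tolerance = 1e-7)
  expect_equal(tr$Pa, trs$Ap, tolerance = 1e-7)
  expect_equal(tr$Pp, trs$Aa, tolerance = 1e-7)
})

test_that("steady-state enumeration matches the regime structure", {
  fps_hi <- find_steady_states(high_fb())
  expect_equal(sum(fps_hi$stability == "stable"), 4)
  # one fixed point per polarity quadrant
  labs <- apply(fps_hi[fps_hi$stability == "stable",
                       c("Aa", "Ap", "Pa", "Pp")], 1,
                classify_quadrant, params = high_fb())
  expect_setequal(labs, c("UNIFORM_A", "UNIFORM_P", "POLARIZED_AP",
                          "POLARIZED_PA"))
  # a single central (fully symmetric) point, not stable
  central <- fps_hi[abs(fps_hi$Aa - fps_hi$Pp) < 1e-8 &
                    abs(fps_hi$Aa - fps_hi$Ap) < 1e-8 &
                    abs(fps_hi$Aa - fps_hi$Pa) < 1e-8, ]
  expect_equal(nrow(central), 1)
  expect_gt(central$max_eig_re, 0)
  # residuals honored
  expect_true(all(fps_hi$residual < 1e-9))

  fps_lo <- find_steady_states(low_fb())
  stable_lo <- fps_lo[fps_lo$stability == "stable", ]
  expect_equal(nrow(stable_lo), 1)
  expect_equal(classify_quadrant(unlist(stable_lo[1, c("Aa", "Ap", "Pa", "Pp")]),
                                 params = low_fb()), "UNIFORM_A")
})

test_that("the no-feedback model has exactly one stable fixed point at the balance", {
  p <- linear_params()
  fps <- find_steady_states(p)
  expect_equal(nrow(fps), 1)
  expect_equal(fps$stability, "stable")
  expect_equal(fps$Aa, linear_balance(p, p$rhoA), tolerance = 1e-9)
  # eigenvalues agree with the explicit linear system
  Jlin <- matrix(0, 4, 4)
  kp2 <- -p$kon * p$psi / 2
  Jlin[1, ] <- c(-p$Dtilde + kp2 - p$koff, p$Dtilde + kp2, 0, 0)
  Jlin[2, ] <- c(p$Dtilde + kp2, -p$Dtilde + kp2 - p$koff, 0, 0)
  Jlin[3, ] <- c(0, 0, -p$Dtilde + kp2 - p$koff, p$Dtilde + kp2)
  Jlin[4, ] <- c(0, 0, p$Dtilde + kp2, -p$Dtilde + kp2 - p$koff)
  st <- unlist(fps[1, c("Aa", "Ap", "Pa", "Pp")])
  names(st) <- c("Aa", "Ap", "Pa", "Pp")
  cl <- classify_stability(st, p)
  expect_equal(cl$label, "stable")
  expect_equal(cl$eigenvalues,
               sort(Re(eigen(Jlin, only.values = TRUE)$values),
                    decreasing = TRUE), tolerance = 1e-8)
})

test_that("stable fixed-point count falls monotonically from 4 to 1 as kAP drops", {
  counts <- vapply(c(50, 5, 1.5, 0.5), function(k)
    sum(find_steady_states(ode_params(kAP = k))$stability == "stable"),
    numeric(1))
  expect_equal(counts[1], 4)
  expect_equal(counts[length(counts)], 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("quadrant classification follows signs with a dead zone", {
  expect_equal(classify_quadrant(c(Aa = 1, Ap = 1, Pa = 0, Pp = 0)),
               "UNIFORM_A")
  expect_equal(classify_quadrant(c(Aa = 0, Ap = 0, Pa = 1, Pp = 1)),
               "UNIFORM_P")
  expect_equal(classify_quadrant(c(Aa = 1, Ap = 0, Pa = 0, Pp = 1)),
               "POLARIZED_AP")
  expect_equal(classify_quadrant(c(Aa = 0, Ap = 1, Pa = 1, Pp = 0)),
               "POLARIZED_PA")
  expect_equal(classify_quadrant(c(Aa = 0, Ap = 0, Pa = 0, Pp = 0)),
               "UNDEFINED")
  # dead zone width is respected
  expect_equal(classify_quadrant(c(Aa = 0.005, Ap = 0.9, Pa = 0, Pp = 0),
                                 dead_zone = 0.01), "UNDEFINED")
})

test_that("root-finder fixed points agree with brute-force integration endpoints", {
  for (regime in c("high_feedback", "low_feedback")) {
    p <- par_regime(regime)
    fps <- find_steady_states(p)
    stable <- as.matrix(fps[fps$stability == "stable",
                            c("Aa", "Ap", "Pa", "Pp")])
    g <- seq(0, 2 * p$rhoA / p$psi, length.out = 3)
    starts <- as.matrix(expand.grid(g, g, g, g))
    adm <- (p$rhoA - p$psi * (starts[, 1] + starts[, 2]) / 2 >= 0) &
           (p$rhoP - p$psi * (starts[, 3] + starts[, 4]) / 2 >= 0)
    starts <- starts[adm, , drop = FALSE]
    for (i in seq_len(nrow(starts))) {
      y0 <- c(Aa = starts[i, 1], Ap = starts[i, 2],
              Pa = starts[i, 3], Pp = starts[i, 4])
      endpoint <- as.numeric(simulate_ode(y0, p, c(0, 2000))[2,
                             c("Aa", "Ap", "Pa", "Pp")])
      dists <- sqrt(colSums((t(as.matrix(fps[, c("Aa", "Ap", "Pa", "Pp")])) -
                               endpoint)^2))
      expect_lt(min(dists), 1e-4)
    }
  }
})
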