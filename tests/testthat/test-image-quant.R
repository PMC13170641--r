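test_that("straightening a rotationally uniform embryo gives identical rows", {
  # circular embryo: every cross-membrane profile is the same
  tr <- embryo_truth(semi_axes_um = c(6, 6), amplitude = 1, noise_sd = 0,
                     margin_px = 60, seed = 1)
  e <- make_embryo_image(tr)
  strip <- straighten_membrane(e$img, e$roi)
  expect_equal(ncol(strip), 100)
  expect_equal(nrow(strip), length(attr(strip, "positions")))
  spread <- apply(strip, 2, function(col) diff(range(col)))
  expect_lt(max(spread), 0.02)  # interpolation tolerance
  # inside columns sit on the cytoplasmic plateau, outside on background
  expect_gt(mean(strip[, 95:100]), mean(strip[, 1:5]))
  expect_error(straighten_membrane(e$img[1:40, ], e$roi), "border")
})

test_that("straightened peak heights track a known angular amplitude function", {
  ampfun <- function(theta) 1 + 0.5 * cos(theta)
  tr <- small_embryo(amplitude = ampfun, seed = 2)
  e <- make_embryo_image(tr)
  strip <- straighten_membrane(e$img, e$roi)
  peaks <- apply(strip, 1, max)
  truth <- tr$amplitude(e$truth_profile$theta) + tr$bg +
    tr$cyto * 0.5  # step at half height under the ridge center
  expect_gt(stats::cor(peaks, truth), 0.99)
})

test_that("rolling average is a circular mean filter", {
  m <- matrix(5, 30, 4)
  expect_equal(rolling_average(m, 10), m, ignore_attr = TRUE)
  imp <- matrix(0, 30, 1); imp[7, 1] <- 1
  out <- rolling_average(imp, 5)
  expect_equal(sum(out), 1)            # conservation on the circle
  expect_equal(sum(out > 1e-12), 5)    # spread over exactly `window` rows
  expect_equal(max(out), 1 / 5)
  # wrap-around: impulse at the first row spreads to the last rows
  imp2 <- matrix(0, 30, 1); imp2[1, 1] <- 1
  out2 <- rolling_average(imp2, 5)
  expect_gt(out2[30, 1], 0)
})

test_that("the cross-profile fit recovers its generating parameters", {
  i <- 1:100
  model <- function(amp, mu, sg, cyto, bg)
    bg + cyto * pnorm((i - mu) / sg) + amp * exp(-(i - mu)^2 / (2 * sg^2))
  # pure constant input: degenerate fit, bg carries the level
  f0 <- fit_cross_profile(rep(3, 100))
  expect_true(f0$converged)
  expect_lt(abs(f0$amplitude), 1e-6)
  expect_lt(abs(f0$cyto), 1e-6)
  expect_equal(f0$bg, 3, tolerance = 1e-6)
  # known parameters + small noise recovered within tolerance
  set.seed(5)
  y <- model(2, 48, 4, 0.8, 0.2) + rnorm(100, sd = 0.02)  # SNR 100
  f <- fit_cross_profile(y)
  expect_true(f$converged)
  expect_equal(f$amplitude, 2, tolerance = 0.02)
  expect_equal(f$mu, 48, tolerance = 0.2)
  expect_equal(f$sigma_g, 4, tolerance = 0.2)
  expect_equal(f$cyto, 0.8, tolerance = 0.1)
  # scale equivariance: doubling intensities doubles the linear parameters
  f2 <- fit_cross_profile(2 * y)
  expect_equal(f2$amplitude, 2 * f$amplitude, tolerance = 1e-3)
  expect_equal(f2$cyto, 2 * f$cyto, tolerance = 1e-3)
  expect_equal(f2$bg, 2 * f$bg, tolerance = 1e-3)
})

test_that("membrane_profile recovers uniform and polarized ground truth", {
  e <- make_embryo_image(small_embryo(amplitude = 1, seed = 3))
  mp <- membrane_profile(e$img, e$roi, fit_every = 4)
  expect_true(all(mp$converged))
  expect_lt(stats::median(abs(mp$amplitude - 1)), 0.03)
  # anterior-half-only amplitude: ASI approaches +0.5
  half <- function(theta) ifelse(cos(theta) > 0, 1, 0)
  e2 <- make_embryo_image(small_embryo(amplitude = half, seed = 4))
  mp2 <- membrane_profile(e2$img, e2$roi, fit_every = 4)
  expect_gt(profile_asi(mp2$amplitude), 0.4)
  # empty membrane: amplitudes near zero
  e3 <- make_embryo_image(small_embryo(amplitude = 0, seed = 5))
  mp3 <- membrane_profile(e3$img, e3$roi, fit_every = 8)
  expect_lt(stats::median(abs(mp3$amplitude), na.rm = TRUE), 0.02)
})

test_that("asi is the exact printed arithmetic with its bounds", {
  expect_equal(asi(1, 1), 0)
  expect_equal(asi(1, 0), 0.5)
  expect_equal(asi(0, 1), -0.5)
  expect_equal(asi(1, 3), -0.25)
  expect_error(asi(0, 0), "undefined")
  expect_error(asi(-1, 2))
  # bounds on random nonnegative pairs
  set.seed(1)
  for (k in 1:50) {
    v <- runif(2, 0, 10)
    expect_true(abs(asi(v[1], v[2])) <= 0.5)
  }
})

test_that("within-series alignment recovers known circular shifts exactly", {
  set.seed(8)
  base <- as.numeric(stats::filter(rnorm(80), rep(1 / 5, 5),
                                   circular = TRUE))
  shifts_true <- c(0, 5, -7, 12, 30)
  profs <- t(vapply(shifts_true, function(k) parosc:::.circshift(base, k),
                    numeric(80)))
  res <- align_profiles_within(profs)
  # aligned profiles all identical up to a global rotation
  expect_lt(res$mse, 1e-20)
  rel <- (res$shifts + shifts_true) %% 80
  expect_equal(length(unique(rel)), 1)  # shifts undo the applied offsets
  expect_true(all(diff(res$mse_path) <= 1e-15))  # MSE non-increasing
  # already-aligned profiles: all shifts zero
  res0 <- align_profiles_within(profs[c(1, 1, 1), ])
  expect_equal(res0$shifts, c(0L, 0L, 0L))
})

test_that("between-embryo alignment flags inverted traversal directions", {
  set.seed(9)
  base <- as.numeric(stats::filter(rnorm(60), rep(1 / 5, 5),
                                   circular = TRUE))
  profs <- rbind(base,
                 parosc:::.circshift(base, 4),
                 rev(base),
                 parosc:::.circshift(rev(base), -9))
  res <- align_profiles_between(profs)
  expect_equal(res$inverted, c(FALSE, FALSE, TRUE, TRUE))
  expect_lt(res$mse, 1e-20)
  # single profile: identity
  res1 <- align_profiles_between(profs[1, , drop = FALSE])
  expect_equal(res1$shifts, 0L)
  expect_false(res1$inverted)
  # adding a constant to one profile does not change the alignment
  profs2 <- profs
  profs2[2, ] <- profs2[2, ] + 3
  res2 <- align_profiles_between(profs2)
  expect_equal(res2$shifts, res$shifts)
  expect_equal(res2$inverted, res$inverted)
})

test_that("difference-of-Gaussians is zero on constants and band-passes blobs", {
  expect_lt(max(abs(dog_subtract(matrix(4, 40, 40), 1, 5))), 1e-9)
  img <- make_cluster_image(positions = matrix(c(30, 30), 1),
                            intensities = 1, sigmas = 2, bg = 0.5,
                            dim = c(60, 60), seed = 1)$img
  bs <- dog_subtract(img, 1, 5)
  expect_gt(bs[30, 30], 0)
  # analytic response at a Gaussian spot center: blur of a Gaussian of width
  # s with sigma is a Gaussian of width sqrt(s^2 + sigma^2), peak scaled by
  # s^2 / (s^2 + sigma^2)
  pred <- 4 / (4 + 1) - 4 / (4 + 25)
  expect_equal(bs[30, 30], pred, tolerance = 0.02)
})

test_that("LoG detection meets the well-separated benchmark and the density identity", {
  ci <- make_cluster_image(n = 25, intensities = 1, sigmas = 2,
                           noise_sd = 0.2, seed = 4)  # SNR 5
  cs <- detect_clusters(dog_subtract(ci$img, 1, 5))
  tp <- 0
  for (i in seq_len(nrow(ci$truth))) {
    d <- sqrt((cs$clusters$x - ci$truth$x[i])^2 +
              (cs$clusters$y - ci$truth$y[i])^2)
    if (length(d) && min(d) <= 1.5) tp <- tp + 1
  }
  expect_gte(tp / nrow(ci$truth), 0.95)                       # recall
  expect_gte(tp / max(1, nrow(cs$clusters)), 0.95)            # precision
  expect_equal(cs$density, sum(cs$clusters$intensity) / cs$cell_area)
  # blank image: no clusters, zero density
  set.seed(10)
  blank <- matrix(rnorm(128 * 128, sd = 0.2), 128, 128)
  cs0 <- detect_clusters(dog_subtract(blank, 1, 5))
  expect_equal(nrow(cs0$clusters), 0L)
  expect_equal(cs0$density, 0)
})
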