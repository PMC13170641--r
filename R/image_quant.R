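#' Straighten the membrane region of an embryo image
#'
#' Resamples a closed contour tracing the membrane at (approximately)
#' 1-pixel arc-length spacing, estimates smoothed local normals, and samples
#' the image along each normal with bilinear interpolation, producing a strip
#' whose rows follow the contour and whose columns run from outside the cell
#' (column 1) to inside (column `width`).
#'
#' @param img numeric matrix of pixel intensities (row = y, column = x).
#' @param roi closed contour as an `n x 2` matrix of `(x, y)` image
#'   coordinates (1-based pixel centers), at least 16 vertices.
#' @param width strip width in pixels (default 100: 50 outside, 50 inside).
#' @param spacing arc-length sampling step along the contour (pixels).
#' @param tangent_window number of resampled points used to smooth the local
#'   tangent.
#' @return A numeric matrix (rows = contour positions, columns = `width`
#'   cross-membrane samples) with attribute `"positions"` (arc length of each
#'   row, pixels).
#' @export
straighten_membrane <- function(img, roi, width = 100, spacing = 1,
                                tangent_window = 5) {
  stopifnot(is.matrix(img), is.matrix(roi), ncol(roi) == 2,
            nrow(roi) >= 16)
  ## resample contour at uniform arc length
  pts <- roi
  if (all(pts[1, ] == pts[nrow(pts), ])) pts <- pts[-nrow(pts), ]
  closed <- rbind(pts, pts[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  s_out <- seq(0, total, by = spacing)
  s_out <- s_out[s_out < total - 1e-9]
  cx <- stats::approx(s, closed[, 1], xout = s_out)$y
  cy <- stats::approx(s, closed[, 2], xout = s_out)$y
  n <- length(s_out)
  ## smoothed tangents on the circular sequence
  half <- max(1L, tangent_window %/% 2)
  ixp <- ((seq_len(n) - 1 + half) %% n) + 1
  ixm <- ((seq_len(n) - 1 - half) %% n) + 1
  tx <- cx[ixp] - cx[ixm]
  ty <- cy[ixp] - cy[ixm]
  len <- sqrt(tx^2 + ty^2)
  tx <- tx / len; ty <- ty / len
  ## outward normal: for a counterclockwise contour (shoelace area > 0 in
  ## standard orientation) the outward normal is (ty, -tx); flip globally if
  ## the polygon is traversed the other way.
  area2 <- sum(closed[-nrow(closed), 1] * closed[-1, 2] -
               closed[-1, 1] * closed[-nrow(closed), 2])
  sgn <- if (area2 > 0) 1 else -1
  nx <- sgn * ty
  ny <- -sgn * tx
  offsets <- seq(-(width / 2) + 0.5, (width / 2) - 0.5, by = 1)
  margin <- width / 2
  if (any(cx - margin < 1) || any(cx + margin > ncol(img)) ||
      any(cy - margin < 1) || any(cy + margin > nrow(img)))
    stop("contour too close to the image border for the requested width")
  strip <- matrix(NA_real_, n, width)
  for (j in seq_along(offsets)) {
    # column 1 is the far outside; offsets increase toward the inside
    px <- cx + nx * (-offsets[j])
    py <- cy + ny * (-offsets[j])
    strip[, j] <- .bilinear(img, px, py)
  }
  attr(strip, "positions") <- s_out
  strip
}

## bilinear interpolation at (x, y) image coordinates (1-based)
.bilinear <- function(img, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1), ncol(img) - 1)
  y0 <- pmin(pmax(y0, 1), nrow(img) - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- img[cbind(y0, x0)]
  i01 <- img[cbind(y0, x0 + 1)]
  i10 <- img[cbind(y0 + 1, x0)]
  i11 <- img[cbind(y0 + 1, x0 + 1)]
  (1 - fy) * ((1 - fx) * i00 + fx * i01) +
    fy * ((1 - fx) * i10 + fx * i11)
}

#' Rolling average along the contour direction
#'
#' Circular (wrap-around) box filter applied down the rows of a straightened
#' strip; the contour is closed, so the filter wraps.
#'
#' @param strip matrix from [straighten_membrane()] (or any matrix whose rows
#'   form a circular sequence).
#' @param window filter width in rows.
#' @return Filtered matrix of the same shape.
#' @export
rolling_average <- function(strip, window = 20) {
  stopifnot(window >= 1, window <= nrow(strip))
  if (window == 1) return(strip)
  out <- apply(strip, 2, function(col)
    as.numeric(stats::filter(col, rep(1 / window, window), sides = 2,
                             circular = TRUE)))
  attr(out, "positions") <- attr(strip, "positions")
  out
}

#' Fit the cross-membrane intensity model to one profile
#'
#' Least-squares fit of `bg + cyto * Phi((i - mu) / sigma_g) +
#' amplitude * exp(-(i - mu)^2 / (2 * sigma_g^2))`, where `Phi` is the
#' standard normal CDF rising toward the cytoplasmic (inside, high-index)
#' end: a Gaussian membrane peak over an error-function cytoplasmic step and
#' a constant background. By default the step shares the Gaussian width
#' (one fewer free parameter); `share_width = FALSE` frees it.
#'
#' @param profile numeric vector of intensities across the membrane
#'   (outside first).
#' @param share_width tie the erf step width to the Gaussian width.
#' @return A one-row data.frame: `amplitude`, `mu`, `sigma_g`, `cyto`, `bg`,
#'   `sigma_e`, `rss`, `converged`. On non-convergence `converged` is `FALSE`
#'   and `amplitude` is `NA`.
#' @export
fit_cross_profile <- function(profile, share_width = TRUE) {
  stopifnot(all(is.finite(profile)))
  n <- length(profile)
  i <- seq_len(n)
  if (stats::sd(profile) < 1e-12)  # degenerate constant input
    return(data.frame(amplitude = 0, mu = n / 2, sigma_g = 3, cyto = 0,
                      bg = mean(profile), sigma_e = 3, rss = 0,
                      converged = TRUE))
  n_edge <- max(3L, round(n * 0.1))
  outer_lvl <- mean(profile[seq_len(n_edge)])
  inner_lvl <- mean(profile[(n - n_edge + 1):n])
  start <- list(amplitude = max(profile) - min(profile),
                mu = n / 2, sigma_g = 3,
                cyto = inner_lvl - outer_lvl, bg = outer_lvl)
  lower <- c(amplitude = 0, mu = 1, sigma_g = 1,
             cyto = -Inf, bg = -Inf)
  upper <- c(amplitude = Inf, mu = n, sigma_g = 15, cyto = Inf, bg = Inf)
  df <- data.frame(i = i, yy = profile)
  fit <- if (share_width) {
    tryCatch(minpack.lm::nlsLM(
      yy ~ bg + cyto * pnorm((i - mu) / sigma_g) +
        amplitude * exp(-(i - mu)^2 / (2 * sigma_g^2)),
      data = df, start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  } else {
    start$sigma_e <- 3
    tryCatch(minpack.lm::nlsLM(
      yy ~ bg + cyto * pnorm((i - mu) / sigma_e) +
        amplitude * exp(-(i - mu)^2 / (2 * sigma_g^2)),
      data = df, start = start,
      lower = c(lower, sigma_e = 1), upper = c(upper, sigma_e = 25),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit))
    return(data.frame(amplitude = NA_real_, mu = NA_real_,
                      sigma_g = NA_real_, cyto = NA_real_, bg = NA_real_,
                      sigma_e = NA_real_, rss = NA_real_,
                      converged = FALSE))
  cf <- stats::coef(fit)
  data.frame(amplitude = cf[["amplitude"]], mu = cf[["mu"]],
             sigma_g = cf[["sigma_g"]], cyto = cf[["cyto"]],
             bg = cf[["bg"]],
             sigma_e = if (share_width) cf[["sigma_g"]] else cf[["sigma_e"]],
             rss = sum(stats::resid(fit)^2), converged = TRUE)
}

#' Quantify the membrane profile of an embryo image
#'
#' Pipeline composition: straighten the membrane, apply the rolling average
#' along the contour, and fit the cross-membrane model at each sampled
#' position. The membrane concentration at each position is the amplitude of
#' the Gaussian component.
#'
#' @param img numeric intensity matrix.
#' @param roi closed contour (`n x 2`, `(x, y)`).
#' @param width strip width (pixels).
#' @param smooth_window rolling-average window (rows).
#' @param fit_every fit every k-th contour position (1 = all).
#' @param pixel_size physical pixel size (micrometres/pixel), used only to
#'   report positions in micrometres.
#' @return A data.frame of class `membrane_profile`: `position` (pixels),
#'   `position_um`, `amplitude`, `mu`, `sigma_g`, `cyto`, `bg`, `rss`,
#'   `converged`. Failed fits carry `NA` amplitude, not zero.
#' @export
membrane_profile <- function(img, roi, width = 100, smooth_window = 20,
                             fit_every = 1, pixel_size = 0.155) {
  strip <- straighten_membrane(img, roi, width = width)
  strip <- rolling_average(strip, window = smooth_window)
  pos <- attr(strip, "positions")
  rows <- seq(1, nrow(strip), by = fit_every)
  fits <- do.call(rbind, lapply(rows, function(r)
    fit_cross_profile(strip[r, ])))
  out <- cbind(data.frame(position = pos[rows],
                          position_um = pos[rows] * pixel_size),
               fits[, c("amplitude", "mu", "sigma_g", "cyto", "bg", "rss",
                        "converged")])
  class(out) <- c("membrane_profile", "data.frame")
  out
}

#' Asymmetry index
#'
#' `ASI = (A - P) / (2 * (A + P))` for summed anterior and posterior
#' signals; 0 for a uniform distribution, +0.5 when all signal is anterior,
#' -0.5 when all is posterior.
#'
#' @param anterior,posterior nonnegative summed signals.
#' @return ASI in `[-0.5, 0.5]`.
#' @export
asi <- function(anterior, posterior) {
  stopifnot(anterior >= 0, posterior >= 0)
  if (anterior + posterior == 0) stop("ASI undefined: A + P = 0")
  (anterior - posterior) / (2 * (anterior + posterior))
}

.circshift <- function(v, k) {
  n <- length(v)
  k <- ((k %% n) + n) %% n
  if (k == 0) v else c(v[(n - k + 1):n], v[seq_len(n - k)])
}

## best integer circular shift of profile onto reference (mean-subtracted
## MSE); returns list(shift, mse)
.best_shift <- function(profile, reference) {
  p <- profile - mean(profile)
  r <- reference - mean(reference)
  n <- length(p)
  mses <- vapply(0:(n - 1), function(k) mean((.circshift(p, k) - r)^2),
                 numeric(1))
  k <- which.min(mses) - 1L
  list(shift = k, mse = mses[k + 1L])
}

#' Align membrane profiles within an embryo time series
#'
#' Iteratively aligns each profile to the running mean by the best integer
#' circular shift (MSE on mean-subtracted profiles), recomputing the mean
#' until the total MSE stops improving. The MSE sequence is non-increasing.
#'
#' @param profiles matrix, one row per time point (equal-length circular
#'   profiles).
#' @param max_iter iteration cap.
#' @param tol minimum MSE improvement to continue.
#' @return List with `shifts` (integer, per profile), `aligned` (matrix),
#'   `mse` (final mean squared error), `mse_path`.
#' @export
align_profiles_within <- function(profiles, max_iter = 50, tol = 1e-12) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  n <- nrow(profiles)
  shifts <- integer(n)
  aligned <- profiles
  mse_path <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    ref <- colMeans(aligned)
    total <- 0
    for (i in seq_len(n)) {
      bs <- .best_shift(profiles[i, ], ref)
      shifts[i] <- bs$shift
      aligned[i, ] <- .circshift(profiles[i, ], bs$shift)
      total <- total + bs$mse
    }
    mse <- total / n
    mse_path <- c(mse_path, mse)
    if (prev - mse < tol) break
    prev <- mse
  }
  list(shifts = shifts, aligned = aligned, mse = mse_path[length(mse_path)],
       mse_path = mse_path)
}

#' Align reference profiles between embryos, with orientation correction
#'
#' Each embryo contributes one reference profile (e.g. the average of frames
#' around NEBD). Profiles are iteratively aligned to the grand mean over both
#' traversal orientations: for each embryo the (orientation, circular shift)
#' pair with the lower mean-subtracted MSE wins, ties broken toward
#' non-inverted, zero shift.
#'
#' @param profiles matrix, one row per embryo.
#' @param max_iter,tol as in [align_profiles_within()].
#' @return List with `shifts`, `inverted` (logical), `aligned`, `mse`,
#'   `mse_path`.
#' @export
align_profiles_between <- function(profiles, max_iter = 50, tol = 1e-12) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1)
  n <- nrow(profiles)
  shifts <- integer(n)
  inverted <- logical(n)
  aligned <- profiles
  mse_path <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    ref <- colMeans(aligned)
    total <- 0
    for (i in seq_len(n)) {
      fwd <- .best_shift(profiles[i, ], ref)
      bwd <- .best_shift(rev(profiles[i, ]), ref)
      if (bwd$mse < fwd$mse - 1e-15) {
        inverted[i] <- TRUE
        shifts[i] <- bwd$shift
        aligned[i, ] <- .circshift(rev(profiles[i, ]), bwd$shift)
        total <- total + bwd$mse
      } else {
        inverted[i] <- FALSE
        shifts[i] <- fwd$shift
        aligned[i, ] <- .circshift(profiles[i, ], fwd$shift)
        total <- total + fwd$mse
      }
    }
    mse <- total / n
    mse_path <- c(mse_path, mse)
    if (prev - mse < tol) break
    prev <- mse
  }
  list(shifts = shifts, inverted = inverted, aligned = aligned,
       mse = mse_path[length(mse_path)], mse_path = mse_path)
}

#' Difference-of-Gaussians background subtraction
#'
#' Band-pass filters an image as `blur(sigma_small) - blur(sigma_large)`;
#' the response to a constant image is zero.
#'
#' @param img numeric matrix.
#' @param sigma_small,sigma_large Gaussian widths in pixels,
#'   `sigma_small < sigma_large`.
#' @return Background-subtracted matrix of the same shape.
#' @export
dog_subtract <- function(img, sigma_small = 1, sigma_large = 5) {
  stopifnot(sigma_small < sigma_large)
  .gblur(img, sigma_small) - .gblur(img, sigma_large)
}

## replicate-pad a matrix by r pixels on each side
.pad_replicate <- function(m, r) {
  m <- rbind(m[rep(1, r), , drop = FALSE], m,
             m[rep(nrow(m), r), , drop = FALSE])
  cbind(m[, rep(1, r), drop = FALSE], m,
        m[, rep(ncol(m), r), drop = FALSE])
}

## convolve with replicate padding (avoids circular wrap artifacts at the
## image borders that FFT filtering would introduce)
.conv_replicate <- function(img, kernel) {
  r <- max(dim(kernel)) %/% 2 + 1L
  mp <- .pad_replicate(img, r)
  out <- EBImage::filter2(mp, kernel)
  out[(r + 1):(r + nrow(img)), (r + 1):(r + ncol(img))]
}

## separable Gaussian blur with replicate padding
.gblur <- function(img, sigma) {
  radius <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  mp <- .pad_replicate(img, radius)
  f <- matrix(k, ncol = 1)
  out <- EBImage::filter2(EBImage::filter2(mp, f), t(f))
  out[(radius + 1):(radius + nrow(img)),
      (radius + 1):(radius + ncol(img))]
}

#' Detect punctate clusters with the Laplacian-of-Gaussian method
#'
#' Computes the scale-normalized LoG response over a range of scales, finds
#' local maxima of the (sign-flipped, so bright blobs are positive) response
#' in space and scale above a threshold, and reports per-cluster position,
#' size (the argmax scale radius `sqrt(2) * sigma`) and intensity (the sum of
#' the background-subtracted image over the cluster footprint). Cluster
#' density is total cluster intensity divided by the visible cell area.
#'
#' @param img_bgsub background-subtracted image (see [dog_subtract()]).
#' @param scales Gaussian scales (pixels) for the LoG stack.
#' @param threshold response threshold; default `6 * mad` of the
#'   finest-scale response.
#' @param cell_mask optional logical matrix marking the visible cell; its
#'   pixel count is the cell area (default: whole image).
#' @return An object of class `cluster_set`: list with `clusters`
#'   (data.frame `x`, `y`, `sigma`, `size`, `intensity`), `cell_area`,
#'   `density`.
#' @export
detect_clusters <- function(img_bgsub, scales = seq(1, 4, by = 0.5),
                            threshold = NULL, cell_mask = NULL) {
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  stack <- lapply(scales, function(s)
    -s^2 * .conv_replicate(.gblur(img_bgsub, s), lap))
  if (is.null(threshold)) {
    # robust noise floor plus a relative floor so near-noise-free images do
    # not admit interpolation ripples as maxima
    peak <- max(vapply(stack, max, numeric(1)), 0)
    threshold <- max(8 * stats::mad(stack[[1]]), 0.02 * peak, 1e-12)
  }
  nr <- nrow(img_bgsub); nc <- ncol(img_bgsub)
  ## local maxima over 3x3 spatial neighborhood and adjacent scales
  shift_max <- function(m) {
    big <- matrix(-Inf, nr + 2, nc + 2)
    big[2:(nr + 1), 2:(nc + 1)] <- m
    out <- matrix(-Inf, nr, nc)
    for (di in 0:2) for (dj in 0:2) {
      cand <- big[(1 + di):(nr + di), (1 + dj):(nc + dj)]
      out <- pmax(out, cand)
    }
    out
  }
  neigh_max <- lapply(stack, shift_max)
  found <- list()
  for (si in seq_along(scales)) {
    m <- stack[[si]]
    nmax <- neigh_max[[si]]
    if (si > 1) nmax <- pmax(nmax, neigh_max[[si - 1]])
    if (si < length(scales)) nmax <- pmax(nmax, neigh_max[[si + 1]])
    hit <- which(m >= nmax - 1e-12 & m > threshold, arr.ind = TRUE)
    if (nrow(hit) > 0)
      found[[length(found) + 1]] <- data.frame(
        y = hit[, 1], x = hit[, 2], sigma = scales[si],
        response = m[hit])
  }
  cell_area <- if (is.null(cell_mask)) nr * nc else sum(cell_mask)
  if (length(found) == 0) {
    cl <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                     size = numeric(0), intensity = numeric(0))
    return(structure(list(clusters = cl, cell_area = cell_area,
                          density = 0), class = "cluster_set"))
  }
  cand <- do.call(rbind, found)
  cand <- cand[order(-cand$response), ]
  ## greedy non-maximum suppression across scales
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1) { keep[1] <- TRUE; next }
    prev <- cand[keep, , drop = FALSE]
    dmin <- sqrt(min((prev$x - cand$x[i])^2 + (prev$y - cand$y[i])^2))
    keep[i] <- dmin > 2 * cand$sigma[i]
  }
  cand <- cand[keep, ]
  intensity <- vapply(seq_len(nrow(cand)), function(i) {
    r <- sqrt(2) * cand$sigma[i]
    xs <- max(1, floor(cand$x[i] - r)):min(nc, ceiling(cand$x[i] + r))
    ys <- max(1, floor(cand$y[i] - r)):min(nr, ceiling(cand$y[i] + r))
    sub <- img_bgsub[ys, xs, drop = FALSE]
    d2 <- outer((ys - cand$y[i])^2, (xs - cand$x[i])^2, "+")
    sum(sub[d2 <= r^2])
  }, numeric(1))
  cl <- data.frame(x = cand$x, y = cand$y, sigma = cand$sigma,
                   size = sqrt(2) * cand$sigma, intensity = intensity)
  structure(list(clusters = cl, cell_area = cell_area,
                 density = sum(intensity) / cell_area),
            class = "cluster_set")
}

#' Read a (multi-page) TIFF image as numeric matrices
#'
#' Thin wrapper around the tiff package; pages are returned as a list of
#' matrices in row-major image orientation.
#'
#' @param path TIFF file path.
#' @return List of numeric matrices (one per page).
#' @export
read_image_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("reading TIFF files requires the 'tiff' package")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    m <- as.matrix(p)
    storage.mode(m) <- "double"
    m
  })
}
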