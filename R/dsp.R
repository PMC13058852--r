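#' Butterworth filter as second-order sections
#'
#' Designs a digital Butterworth filter (low-pass, high-pass or band-pass) by
#' bilinear transform of the analog prototype and returns it as a cascade of
#' second-order sections (biquads). The cascade form stays numerically stable
#' at very low normalized cutoffs (e.g. 0.01 Hz at 2.5 Hz sampling), where the
#' expanded transfer-function polynomial form does not.
#'
#' @param order Filter order (for `"band"`, the prototype order; the final
#'   filter has `2 * order` poles).
#' @param cutoff_Hz Cutoff frequency in Hz (length 1), or the two band edges
#'   for `type = "band"`.
#' @param fs_Hz Sampling rate in Hz.
#' @param type One of `"low"`, `"high"`, `"band"`.
#' @return An object of class `butter_sos`: a list with the section matrix
#'   `sos` (n_sections x 6, columns b0 b1 b2 a0 a1 a2), and the design
#'   parameters.
#' @export
butter_sos <- function(order, cutoff_Hz, fs_Hz,
                       type = c("low", "high", "band")) {
  type <- match.arg(type)
  stopifnot(order >= 1, fs_Hz > 0)
  if (type == "band") {
    if (length(cutoff_Hz) != 2L || diff(cutoff_Hz) <= 0)
      stop("band-pass design needs two increasing cutoff frequencies")
  } else if (length(cutoff_Hz) != 1L) {
    stop("low/high-pass design needs a single cutoff frequency")
  }
  if (any(cutoff_Hz <= 0) || any(cutoff_Hz >= fs_Hz / 2))
    stop("cutoff frequencies must lie strictly inside (0, fs/2)")

  fs2 <- 2 * fs_Hz
  # analog Butterworth prototype poles on the unit circle, left half plane
  k <- seq_len(order)
  theta <- pi * (2 * k - 1) / (2 * order)
  p_proto <- complex(real = -sin(theta), imaginary = cos(theta))

  warp <- function(f) fs2 * tan(pi * f / fs_Hz)
  if (type == "low") {
    wc <- warp(cutoff_Hz)
    p_a <- wc * p_proto
    z_dig_val <- -1
    n_zeros <- order
    w_ref <- 0
  } else if (type == "high") {
    wc <- warp(cutoff_Hz)
    p_a <- wc / p_proto
    z_dig_val <- 1
    n_zeros <- order
    w_ref <- pi
  } else {
    w1 <- warp(cutoff_Hz[1]); w2 <- warp(cutoff_Hz[2])
    bw <- w2 - w1; w0 <- sqrt(w1 * w2)
    # low-pass to band-pass: each prototype pole maps to a quadratic pair
    pb <- p_proto * bw / 2
    disc <- sqrt(pb^2 - w0^2)
    p_a <- c(pb + disc, pb - disc)
    z_dig_val <- NULL # n zeros at z = +1 and n at z = -1
    n_zeros <- order
    w_ref <- 2 * atan(w0 / fs2)
  }

  # bilinear transform of poles
  p_d <- (fs2 + p_a) / (fs2 - p_a)

  # digital zeros are all real (+1 / -1)
  zeros <- if (type == "band") c(rep(1, order), rep(-1, order))
           else rep(z_dig_val, n_zeros)

  # group poles into conjugate pairs (plus possibly real poles)
  tol <- 1e-9
  cplx <- p_d[Im(p_d) > tol]
  reals <- Re(p_d[abs(Im(p_d)) <= tol])
  n_sec <- length(cplx) + ceiling(length(reals) / 2)
  sos <- matrix(0, nrow = n_sec, ncol = 6)
  s <- 0L
  for (p in cplx) {
    s <- s + 1L
    sos[s, 4:6] <- c(1, -2 * Re(p), Mod(p)^2)
  }
  while (length(reals) >= 2L) {
    s <- s + 1L
    sos[s, 4:6] <- c(1, -(reals[1] + reals[2]), reals[1] * reals[2])
    reals <- reals[-(1:2)]
  }
  if (length(reals) == 1L) {
    s <- s + 1L
    sos[s, 4:6] <- c(1, -reals[1], 0)
  }

  # distribute zeros two per section; band-pass gets one of each sign
  zpos <- sum(zeros > 0); zneg <- sum(zeros < 0)
  for (i in seq_len(n_sec)) {
    take <- c()
    if (type == "band") {
      if (zpos > 0) { take <- c(take, 1); zpos <- zpos - 1 }
      if (zneg > 0) { take <- c(take, -1); zneg <- zneg - 1 }
    } else {
      avail <- zpos + zneg
      n_take <- min(2L, avail, if (sos[i, 6] == 0) 1L else 2L)
      if (n_take >= 1) take <- rep(zeros[1], n_take)
      if (zeros[1] > 0) zpos <- zpos - n_take else zneg <- zneg - n_take
    }
    if (length(take) == 2L) {
      sos[i, 1:3] <- c(1, -(take[1] + take[2]), take[1] * take[2])
    } else if (length(take) == 1L) {
      sos[i, 1:3] <- c(1, -take[1], 0)
    } else {
      sos[i, 1:3] <- c(1, 0, 0)
    }
  }

  # normalize overall magnitude to 1 at the reference frequency
  H <- sos_response(sos, w_ref)
  sos[1, 1:3] <- sos[1, 1:3] / Mod(H)

  structure(list(sos = sos, order = order, cutoff_Hz = cutoff_Hz,
                 fs_Hz = fs_Hz, type = type),
            class = "butter_sos")
}

# complex frequency response of an SOS cascade at radian frequency w
sos_response <- function(sos, w) {
  z1 <- exp(-1i * w); z2 <- exp(-2i * w)
  H <- 1 + 0i
  for (i in seq_len(nrow(sos))) {
    num <- sos[i, 1] + sos[i, 2] * z1 + sos[i, 3] * z2
    den <- sos[i, 4] + sos[i, 5] * z1 + sos[i, 6] * z2
    H <- H * num / den
  }
  H
}

# one-pass SOS filtering along the first dimension of a vector or matrix
# (direct form II transposed, vectorized over columns; complex input allowed).
# With steady_init the section states start at the steady-state response to a
# constant equal to the first sample, so a constant input produces a constant
# output (the usual filtfilt initial-condition treatment); without it the
# states start at zero.
sos_filter <- function(x, filt, steady_init = FALSE) {
  sos <- if (inherits(filt, "butter_sos")) filt$sos else filt
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x); m <- ncol(x)
  zero <- if (is.complex(x)) 0+0i else 0
  y <- x
  for (s in seq_len(nrow(sos))) {
    b0 <- sos[s, 1]; b1 <- sos[s, 2]; b2 <- sos[s, 3]
    a1 <- sos[s, 5]; a2 <- sos[s, 6]
    if (steady_init) {
      x1 <- y[1, ]
      hdc <- (b0 + b1 + b2) / (1 + a1 + a2)
      w1 <- (hdc - b0) * x1
      w2 <- (b2 - a2 * hdc) * x1
    } else {
      w1 <- rep(zero, m); w2 <- rep(zero, m)
    }
    for (t in seq_len(n)) {
      xt <- y[t, ]
      yt <- b0 * xt + w1
      w1 <- b1 * xt - a1 * yt + w2
      w2 <- b2 * xt - a2 * yt
      y[t, ] <- yt
    }
  }
  if (vec) drop(y) else y
}

#' Zero-phase (forward-backward) Butterworth filtering
#'
#' Applies an SOS Butterworth filter forward and backward along the first
#' dimension, after odd-reflection padding at both ends to suppress edge
#' transients. The effective magnitude response is the square of the one-pass
#' response and the phase response is zero.
#'
#' @param x Numeric or complex vector, or matrix with time along rows.
#' @param filt A [butter_sos()] design.
#' @param padlen Number of padding samples at each end; defaults to three
#'   times the nominal filter length, capped at `nrow(x) - 1`.
#' @return Filtered data, same shape as `x`.
#' @export
filtfilt_sos <- function(x, filt, padlen = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  n_coef <- 2 * nrow(filt$sos) + 1
  if (is.null(padlen)) padlen <- 3 * n_coef
  if (n <= padlen)
    stop("series too short for zero-phase filtering: need more than ",
         padlen, " samples, got ", n)
  pre <- 2 * x[rep(1, padlen), , drop = FALSE] -
    x[(padlen + 1):2, , drop = FALSE]
  post <- 2 * x[rep(n, padlen), , drop = FALSE] -
    x[(n - 1):(n - padlen), , drop = FALSE]
  ext <- rbind(pre, x, post)
  ext <- sos_filter(ext, filt, steady_init = TRUE)
  ext <- ext[nrow(ext):1, , drop = FALSE]
  ext <- sos_filter(ext, filt, steady_init = TRUE)
  ext <- ext[nrow(ext):1, , drop = FALSE]
  out <- ext[(padlen + 1):(padlen + n), , drop = FALSE]
  if (vec) drop(out) else out
}

# spatial median filter with replicated edges; x is a 2D or 3D array,
# kernel an odd width applied along every spatial axis
median_filter_spatial <- function(x, kernel = 3L) {
  if (kernel <= 1L) return(x)
  if (kernel %% 2L == 0L) stop("median filter kernel must be odd")
  d <- dim(x)
  if (is.null(d)) stop("median filter expects a 2D or 3D array")
  r <- (kernel - 1L) %/% 2L
  offs <- -r:r
  idx <- lapply(d, function(n) seq_len(n))
  # gather shifted copies with edge replication, take per-voxel median
  grids <- expand.grid(rep(list(offs), length(d)))
  stack <- matrix(0, nrow = prod(d), ncol = nrow(grids))
  for (g in seq_len(nrow(grids))) {
    sh <- as.numeric(grids[g, ])
    ii <- lapply(seq_along(d), function(a) pmin(pmax(idx[[a]] + sh[a], 1L), d[a]))
    stack[, g] <- as.vector(do.call(`[`, c(list(x), ii)))
  }
  out <- apply(stack, 1, stats::median)
  array(out, dim = d)
}

# separable Gaussian smoothing of a 2D/3D array, sigma in voxels per axis,
# replicated edges; kernel truncated at 3 sigma and renormalized
gaussian_smooth_array <- function(x, sigma_vox) {
  d <- dim(x)
  sigma_vox <- rep(sigma_vox, length.out = length(d))
  for (a in seq_along(d)) {
    s <- sigma_vox[a]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-((-r:r)^2) / (2 * s^2))
    kern <- kern / sum(kern)
    x <- convolve_axis_replicate(x, kern, a)
  }
  x
}

convolve_axis_replicate <- function(x, kern, axis) {
  d <- dim(x)
  r <- (length(kern) - 1L) %/% 2L
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  dp <- dim(xp)
  m <- matrix(xp, nrow = dp[1])
  n <- nrow(m)
  pad_top <- m[rep(1, r), , drop = FALSE]
  pad_bot <- m[rep(n, r), , drop = FALSE]
  ext <- rbind(pad_top, m, pad_bot)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kern)) {
    out <- out + kern[j] * ext[j:(j + n - 1), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}
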