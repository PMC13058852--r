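#' Spatial quality-control maps
#'
#' Three per-voxel summary volumes used to assess an acquisition at a
#' glance: the temporal mean power Doppler intensity, the temporal
#' coefficient of variation (standard deviation over mean, dimensionless),
#' and the temporal mean absolute axial velocity (mm/s). High coefficient of
#' variation and high mean velocity mark voxels dominated by residual
#' clutter or motion rather than perfusion.
#'
#' @param pd A power Doppler [fusi_series()].
#' @param vel A matching velocity [fusi_series()] (same frame count & grid).
#' @return A `spatial_qc` list with `mean_pd`, `cv`, `mean_velocity` arrays.
#' @export
spatial_qc <- function(pd, vel) {
  if (!identical(dim(pd$data), dim(vel$data)))
    stop("pd and vel must share frame count and grid")
  grid <- dim(pd$data)[-1]
  m <- series_matrix(pd)
  mu <- colMeans(m)
  # population standard deviation: CV of n repeated values is closed-form
  sdv <- sqrt(colMeans(m^2) - mu^2)
  cv <- ifelse(mu > 0, sdv / mu, 0)
  structure(list(mean_pd = array(mu, grid), cv = array(cv, grid),
                 mean_velocity = array(colMeans(series_matrix(vel)), grid)),
            class = "spatial_qc")
}

#' Decibel rendering of a power Doppler volume
#'
#' `10 * log10(x / max(x))`, for display only; all computations in the
#' package stay on the linear scale.
#'
#' @param x Nonnegative array.
#' @return Array of dB values (<= 0), `-Inf` where `x` is 0.
#' @export
pd_to_db <- function(x) 10 * log10(x / max(x))

#' Relative global power Doppler signal (rGS)
#'
#' The global signal GS is the per-frame mean power Doppler over brain
#' voxels; rGS expresses it as percent change over a robust baseline, the
#' first decile of GS: `rGS = 100 * (GS - D1) / D1`. Quantiles use linear
#' interpolation between order statistics (type 7), as everywhere in the
#' package.
#'
#' @param pd A power Doppler [fusi_series()].
#' @param brain_mask Logical spatial mask (or voxel indices).
#' @return Numeric vector of percent values, one per frame.
#' @export
rgs <- function(pd, brain_mask) {
  idx <- mask_indices(brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  gs <- rowMeans(series_matrix(pd)[, idx, drop = FALSE])
  d1 <- stats::quantile(gs, 0.1, type = 7, names = FALSE)
  if (d1 <= 0) stop("degenerate rGS baseline: first decile of GS is <= 0")
  100 * (gs - d1) / d1
}

#' Global axial velocity (GV)
#'
#' Per-frame mean of the absolute axial velocity over brain voxels (mm/s).
#' A direct, intensity-independent measure of brain motion.
#'
#' @param vel A velocity [fusi_series()].
#' @param brain_mask Logical spatial mask (or voxel indices).
#' @return Numeric vector (mm/s), one value per frame.
#' @export
gv <- function(vel, brain_mask) {
  idx <- mask_indices(brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  rowMeans(abs(series_matrix(vel)[, idx, drop = FALSE]))
}

#' Standardized DVARS (rDVARS)
#'
#' DVARS is the root mean square of the backward frame-to-frame signal
#' change over brain voxels. It is standardized by the null level expected
#' from the temporal noise alone, estimated under an AR(1) noise model:
#' `mu0 = mean_v 2 * (1 - rho_v) * sigma_v^2`, with `sigma_v` robustly
#' estimated as `IQR / 1.349` and `rho_v` the sample lag-1 autocorrelation
#' clipped to `[0, 0.99]`. The returned series is `DVARS / sqrt(mu0)`, so
#' that its square has unit expectation under the null and a quiet
#' acquisition fluctuates around 1. The first frame has no backward
#' difference and is returned as `NA`.
#'
#' @param pd A power Doppler [fusi_series()] with at least 3 frames.
#' @param brain_mask Logical spatial mask (or voxel indices).
#' @return Numeric vector, one value per frame (first `NA`).
#' @export
rdvars <- function(pd, brain_mask) {
  idx <- mask_indices(brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  x <- series_matrix(pd)[, idx, drop = FALSE]
  nt <- nrow(x)
  if (nt < 3L) stop("rDVARS needs at least 3 frames")
  d <- x[-1, , drop = FALSE] - x[-nt, , drop = FALSE]
  dvars <- sqrt(rowMeans(d^2))
  sig <- apply(x, 2, stats::IQR, type = 7) / 1.349
  xc <- sweep(x, 2, colMeans(x))
  denom <- colSums(xc^2)
  rho <- ifelse(denom > 0,
                colSums(xc[-1, , drop = FALSE] * xc[-nt, , drop = FALSE]) /
                  denom, 0)
  rho <- pmin(pmax(rho, 0), 0.99)
  mu0 <- mean(2 * (1 - rho) * sig^2)
  if (mu0 <= 0) {
    if (all(dvars == 0)) return(c(NA_real_, dvars))
    stop("degenerate rDVARS noise level: mu0 is not positive")
  }
  c(NA_real_, dvars / sqrt(mu0))
}

#' Temporal quality-control table
#'
#' Computes the three temporal QC metrics (rGS, GV, rDVARS) and returns them
#' as one table with frame index and time, ready to be written as TSV.
#'
#' @param pd A power Doppler [fusi_series()].
#' @param vel The matching velocity [fusi_series()].
#' @param brain_mask Logical spatial mask.
#' @return A data.frame with columns `frame`, `t_sec`, `rgs_pct`, `gv_mm_s`,
#'   `rdvars`.
#' @export
temporal_qc <- function(pd, vel, brain_mask) {
  if (n_frames(pd) != n_frames(vel))
    stop("pd and vel must share the frame count")
  n <- n_frames(pd)
  data.frame(frame = seq_len(n), t_sec = (seq_len(n) - 1) / pd$fs_Hz,
             rgs_pct = rgs(pd, brain_mask), gv_mm_s = gv(vel, brain_mask),
             rdvars = rdvars(pd, brain_mask))
}

#' Mean volumes over intensity-extreme frames
#'
#' Reporting helper: averages power Doppler (and optionally velocity) over
#' the frames with the lowest and highest global intensity (default: bottom
#' and top 5\%), plus their relative difference — the standard way to
#' visualize where motion surges concentrate spatially.
#'
#' @param pd A power Doppler [fusi_series()].
#' @param vel Optional matching velocity series.
#' @param brain_mask Logical spatial mask used to rank frames.
#' @param fraction Fraction of frames in each extreme group.
#' @return A list of arrays: `pd_low`, `pd_high`, `pd_rel_diff`, and when
#'   `vel` is given, `vel_low`, `vel_high`.
#' @export
intensity_extreme_means <- function(pd, vel = NULL, brain_mask, fraction = 0.05) {
  idx <- mask_indices(brain_mask)
  gs <- rowMeans(series_matrix(pd)[, idx, drop = FALSE])
  n <- length(gs)
  k <- max(1L, floor(fraction * n))
  ord <- order(gs)
  lo <- ord[seq_len(k)]; hi <- ord[(n - k + 1):n]
  grid <- dim(pd$data)[-1]
  m <- series_matrix(pd)
  pd_low <- array(colMeans(m[lo, , drop = FALSE]), grid)
  pd_high <- array(colMeans(m[hi, , drop = FALSE]), grid)
  out <- list(pd_low = pd_low, pd_high = pd_high,
              pd_rel_diff = (pd_high - pd_low) / pmax(pd_low, .Machine$double.eps))
  if (!is.null(vel)) {
    mv <- series_matrix(vel)
    out$vel_low <- array(colMeans(mv[lo, , drop = FALSE]), grid)
    out$vel_high <- array(colMeans(mv[hi, , drop = FALSE]), grid)
  }
  out
}
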