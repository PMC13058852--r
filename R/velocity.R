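#' Axial velocity from I/Q phase shifts (Kasai autocorrelation)
#'
#' Estimates the axial scatterer velocity at every voxel and adjacent frame
#' pair of a compound block from the phase of the lag-1 temporal
#' autocorrelation of the beamformed I/Q signal:
#' `v_z = arg(IQ(t+1) * Conj(IQ(t))) * c * f_iq / (4 * pi * f_pulse)`.
#' Computing the argument of the complex product (rather than differencing
#' phases) avoids 2*pi wrap errors. The I/Q signal is optionally low-pass
#' filtered along time before estimation, and each velocity volume is
#' spatially median filtered, both of which suppress estimator noise.
#'
#' @param block An [iq_block()].
#' @param lowpass_cutoff_Hz Temporal low-pass cutoff applied to the I/Q data
#'   before estimation (Hz); `NULL` or `0` disables it.
#' @param lowpass_order Butterworth order of the temporal low-pass.
#' @param median_kernel Width of the spatial median filter applied to each
#'   velocity volume (odd; 1 disables). For 2D acquisitions the kernel is
#'   2D; edges are handled by replication.
#' @return Numeric array of per-pair velocities in mm/s, dimension
#'   (block_len - 1, spatial dims). Values are signed; positive is motion
#'   toward increasing depth.
#' @export
kasai_axial_velocity <- function(block, lowpass_cutoff_Hz = 30,
                                 lowpass_order = 6, median_kernel = 3L) {
  if (!inherits(block, "iq_block")) stop("block must be an iq_block")
  L <- block_len(block)
  if (L < 2L) stop("block must contain at least 2 frames")
  m <- block_matrix(block)
  if (!all(is.finite(Re(m))) || !all(is.finite(Im(m))))
    stop("block contains non-finite samples")
  if (!is.null(lowpass_cutoff_Hz) && lowpass_cutoff_Hz > 0) {
    if (lowpass_cutoff_Hz >= block$f_iq_Hz / 2)
      stop("lowpass_cutoff_Hz must be below the Nyquist frequency")
    lp <- butter_sos(lowpass_order, lowpass_cutoff_Hz, block$f_iq_Hz, "low")
    m <- filtfilt_sos(m, lp, padlen = min(
      ceiling(3 * block$f_iq_Hz / lowpass_cutoff_Hz), L - 1))
  }
  lag1 <- m[2:L, , drop = FALSE] * Conj(m[1:(L - 1), , drop = FALSE])
  dphi <- Arg(lag1)
  v <- dphi * block$c_m_per_s * block$f_iq_Hz /
    (4 * pi * block$f_pulse_Hz) * 1000  # m/s -> mm/s
  grid <- grid_shape(block)
  v <- array(v, dim = c(L - 1, grid))
  if (!is.null(median_kernel) && median_kernel > 1L) {
    for (t in seq_len(L - 1)) {
      if (length(grid) == 2L) {
        v[t, , ] <- median_filter_spatial(array(v[t, , ], grid), median_kernel)
      } else {
        v[t, , , ] <- median_filter_spatial(array(v[t, , , ], grid),
                                            median_kernel)
      }
    }
  }
  v
}

#' Per-block absolute axial velocity volume
#'
#' Averages the absolute value of the per-pair velocity estimates across a
#' block, producing one nonnegative velocity volume per block at the power
#' Doppler sampling rate.
#'
#' @param velocity_frames Output of [kasai_axial_velocity()]: array with
#'   frame pairs along the first dimension.
#' @return Nonnegative array over the spatial grid (mm/s).
#' @export
block_absolute_velocity <- function(velocity_frames) {
  d <- dim(velocity_frames)
  if (is.null(d) || d[1] < 1L) stop("need at least one velocity frame")
  m <- matrix(abs(velocity_frames), nrow = d[1])
  array(colMeans(m), dim = d[-1])
}

#' Absolute axial velocity series for a whole acquisition
#'
#' Runs the Kasai estimator on every block and stacks the per-block absolute
#' velocity volumes into a series at the power Doppler rate.
#'
#' @param blocks List of [iq_block()] objects.
#' @param inter_block_delay_s Dead time after each block (s); shifts the
#'   series rate exactly as it shifts the power Doppler rate.
#' @inheritParams kasai_axial_velocity
#' @return A [fusi_series()] of kind `"velocity"` (mm/s).
#' @export
velocity_series <- function(blocks, lowpass_cutoff_Hz = 30,
                            lowpass_order = 6, median_kernel = 3L,
                            inter_block_delay_s = 0) {
  if (!length(blocks)) stop("need at least one block")
  vols <- lapply(blocks, function(b)
    block_absolute_velocity(kasai_axial_velocity(
      b, lowpass_cutoff_Hz, lowpass_order, median_kernel)))
  grid <- dim(vols[[1]])
  m <- matrix(unlist(vols), ncol = length(vols))
  data <- array(t(m), dim = c(length(vols), grid))
  fs <- pd_frame_rate(blocks[[1]]$f_iq_Hz, block_len(blocks[[1]]),
                      inter_block_delay_s)
  fusi_series(data, fs_Hz = fs, voxel_size_mm = blocks[[1]]$voxel_size_mm,
              kind = "velocity")
}

#' Doppler relations and acquisition timing
#'
#' Small closed-form helpers tying acquisition parameters together:
#' the axial velocity corresponding to a Doppler frequency
#' (`v = f_d * c / (2 * f_pulse)`), its inverse, the Nyquist velocity of the
#' estimator (`c * f_iq / (4 * f_pulse)`), the compound frame rate obtained
#' from a pulse repetition frequency spread over `n_angles` tilted plane
#' waves, and the power Doppler frame rate of `block_len`-frame blocks with
#' an optional inter-block dead time.
#'
#' @param f_d_Hz Doppler frequency (Hz).
#' @param f_pulse_Hz Transmitted pulse frequency (Hz).
#' @param c_m_per_s Speed of sound (m/s).
#' @return `doppler_velocity`: velocity in mm/s.
#' @export
doppler_velocity <- function(f_d_Hz, f_pulse_Hz, c_m_per_s = 1540) {
  f_d_Hz * c_m_per_s / (2 * f_pulse_Hz) * 1000
}

#' @rdname doppler_velocity
#' @param v_mm_s Axial velocity (mm/s).
#' @export
doppler_frequency <- function(v_mm_s, f_pulse_Hz, c_m_per_s = 1540) {
  2 * f_pulse_Hz * (v_mm_s / 1000) / c_m_per_s
}

#' @rdname doppler_velocity
#' @param f_iq_Hz Compound frame rate (Hz).
#' @export
nyquist_velocity <- function(f_iq_Hz, f_pulse_Hz, c_m_per_s = 1540) {
  c_m_per_s * f_iq_Hz / (4 * f_pulse_Hz) * 1000
}

#' @rdname doppler_velocity
#' @param prf_Hz Pulse repetition frequency (Hz).
#' @param n_angles Number of tilted plane waves per compound frame.
#' @export
compound_frame_rate <- function(prf_Hz, n_angles) prf_Hz / n_angles

#' @rdname doppler_velocity
#' @param block_len Compound frames per power Doppler block.
#' @param inter_block_delay_s Dead time after each block (s).
#' @export
pd_frame_rate <- function(f_iq_Hz, block_len, inter_block_delay_s = 0) {
  1 / (block_len / f_iq_Hz + inter_block_delay_s)
}
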