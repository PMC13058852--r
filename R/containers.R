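#' Beamformed I/Q compound block
#'
#' One compound block of complex beamformed ultrasound samples, stored
#' time-first as an array of dimension (frame, z, x) or (frame, z, x, y).
#' The phase of the lag-1 temporal autocorrelation of these samples carries
#' axial scatterer motion; their squared modulus, after clutter filtering,
#' integrates to one power Doppler volume.
#'
#' @param samples Complex array, first dimension time (>= 2 frames).
#' @param f_pulse_Hz Transmitted ultrasound pulse frequency (Hz).
#' @param c_m_per_s Speed of sound (m/s).
#' @param f_iq_Hz Compound frame rate of the beamformed I/Q samples (Hz).
#' @param voxel_size_mm Isotropic voxel spacing (mm).
#' @return An `iq_block` object.
#' @export
iq_block <- function(samples, f_pulse_Hz, c_m_per_s = 1540, f_iq_Hz = 500,
                     voxel_size_mm = 0.1) {
  if (is.null(dim(samples)) || length(dim(samples)) < 2L)
    stop("samples must be an array with time as the first dimension")
  if (dim(samples)[1] < 2L)
    stop("block_len must be at least 2 frames")
  if (!all(is.finite(Re(samples))) || !all(is.finite(Im(samples))))
    stop("samples contain non-finite values")
  stopifnot(f_pulse_Hz > 0, c_m_per_s > 0, f_iq_Hz > 0, voxel_size_mm > 0)
  structure(list(samples = as.complex(samples) |> array(dim = dim(samples)),
                 f_pulse_Hz = f_pulse_Hz, c_m_per_s = c_m_per_s,
                 f_iq_Hz = f_iq_Hz, voxel_size_mm = voxel_size_mm),
            class = "iq_block")
}

#' @export
print.iq_block <- function(x, ...) {
  d <- dim(x$samples)
  cat("<iq_block> ", d[1], " frames, grid ",
      paste(d[-1], collapse = " x "),
      ", f_iq ", x$f_iq_Hz, " Hz, f_pulse ", x$f_pulse_Hz / 1e6, " MHz\n",
      sep = "")
  invisible(x)
}

block_len <- function(block) dim(block$samples)[1]
grid_shape <- function(block) dim(block$samples)[-1]

# (time x voxels) complex matrix view of a block
block_matrix <- function(block) {
  s <- block$samples
  d <- dim(s)
  matrix(s, nrow = d[1], ncol = prod(d[-1]))
}

#' Time series volume container (power Doppler or axial velocity)
#'
#' A 3D+t (or 2D+t) series stored time-first: `data` has dimension
#' (frame, z, x) or (frame, z, x, y). Power Doppler values are nonnegative
#' intensities proportional to cerebral blood volume; velocity values are
#' nonnegative absolute axial velocities in mm/s.
#'
#' @param data Numeric array, first dimension time.
#' @param fs_Hz Frame rate of the series (Hz), e.g. 2.5 for 200-frame blocks
#'   at 500 Hz compounding.
#' @param voxel_size_mm Isotropic voxel spacing (mm).
#' @param kind `"pd"` or `"velocity"`.
#' @return A `fusi_series` object.
#' @export
fusi_series <- function(data, fs_Hz, voxel_size_mm = 0.1,
                        kind = c("pd", "velocity")) {
  kind <- match.arg(kind)
  if (is.null(dim(data)) || length(dim(data)) < 2L)
    stop("data must be an array with time as the first dimension")
  if (!all(is.finite(data))) stop("data contains non-finite values")
  stopifnot(fs_Hz > 0, voxel_size_mm > 0)
  structure(list(data = data, fs_Hz = fs_Hz, voxel_size_mm = voxel_size_mm,
                 kind = kind),
            class = "fusi_series")
}

#' @export
print.fusi_series <- function(x, ...) {
  d <- dim(x$data)
  cat("<fusi_series:", x$kind, "> ", d[1], " frames, grid ",
      paste(d[-1], collapse = " x "), ", ", x$fs_Hz, " Hz, voxel ",
      x$voxel_size_mm, " mm\n", sep = "")
  invisible(x)
}

n_frames <- function(x) dim(x$data)[1]

# (time x voxels) matrix view and its inverse
series_matrix <- function(x) {
  d <- dim(x$data)
  matrix(x$data, nrow = d[1], ncol = prod(d[-1]))
}

series_from_matrix <- function(template, m) {
  out <- template
  out$data <- array(m, dim = c(nrow(m), dim(template$data)[-1]))
  out
}

# flatten a logical spatial mask to linear voxel indices
mask_indices <- function(mask) {
  if (is.logical(mask)) which(mask) else as.integer(mask)
}
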