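#' Denoising strategy
#'
#' One point of the factorial benchmark grid: a clutter filter, a scrubbing
#' metric, a frequency filter, and a confound-regression method, plus the
#' fixed smoothing kernel. The combination of an adaptive constant-energy
#' clutter filter with rGS-based scrubbing is rejected: the adaptive filter
#' flattens the global signal, which makes an rGS threshold blind to motion.
#'
#' @param clutter A [clutter_filter_spec()].
#' @param scrub_metric One of `"rgs"`, `"rdvars"`, `"gv"`, `"none"`.
#' @param freq_filter `"highpass"` (0.01 Hz) or `"bandpass"` (0.01-0.1 Hz).
#' @param confound_method One of `"none"`, `"global_signal"`, `"tcompcor"`,
#'   `"acompcor"`, `"random_compcor"`, `"lowvar_compcor"`.
#' @param n_components Number of principal components for CompCor variants.
#' @param smoothing_fwhm_mm Gaussian smoothing kernel, full width at half
#'   maximum in mm.
#' @param filter_order Butterworth order of the frequency filter.
#' @param thresholds Scrubbing thresholds: percent for rGS, dimensionless
#'   for rDVARS, and mm/s *above the first-decile baseline* for GV.
#' @return A `denoise_strategy` object.
#' @export
denoise_strategy <- function(clutter = clutter_filter_spec("static", 60L),
                             scrub_metric = c("none", "rgs", "rdvars", "gv"),
                             freq_filter = c("highpass", "bandpass"),
                             confound_method = c("none", "global_signal",
                                                 "tcompcor", "acompcor",
                                                 "random_compcor",
                                                 "lowvar_compcor"),
                             n_components = 5L, smoothing_fwhm_mm = 0.3,
                             filter_order = 6L,
                             thresholds = list(rgs = 10, rdvars = 2,
                                               gv = 0.01)) {
  scrub_metric <- match.arg(scrub_metric)
  freq_filter <- match.arg(freq_filter)
  confound_method <- match.arg(confound_method)
  if (clutter$method == "constant_energy" && scrub_metric == "rgs")
    stop("forbidden strategy: constant-energy clutter filtering flattens ",
         "the global signal, so rGS-based scrubbing is ineffective")
  if (any(unlist(thresholds) <= 0)) stop("scrub thresholds must be positive")
  structure(list(clutter = clutter, scrub_metric = scrub_metric,
                 freq_filter = freq_filter,
                 confound_method = confound_method,
                 n_components = as.integer(n_components),
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 filter_order = as.integer(filter_order),
                 thresholds = thresholds),
            class = "denoise_strategy")
}

#' @export
print.denoise_strategy <- function(x, ...) {
  cat("<denoise_strategy> ", x$clutter$method, "_", x$clutter$T_count,
      if (x$clutter$use_brain_mask) "+mask" else "", " | scrub=",
      x$scrub_metric, " | ", x$freq_filter, " | confound=",
      x$confound_method, "\n", sep = "")
  invisible(x)
}

#' Spatial Gaussian smoothing of a series
#'
#' Smooths every frame with an isotropic Gaussian kernel given by its full
#' width at half maximum; `sigma = fwhm / (2 * sqrt(2 * log(2)))` converted
#' to voxels. Edges are replicated. `fwhm_mm = 0` is the identity.
#'
#' @param pd A [fusi_series()].
#' @param fwhm_mm Kernel FWHM in mm.
#' @return Smoothed [fusi_series()].
#' @export
gaussian_smooth <- function(pd, fwhm_mm = 0.3) {
  if (fwhm_mm < 0) stop("fwhm_mm must be nonnegative")
  if (fwhm_mm == 0) return(pd)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / pd$voxel_size_mm
  grid <- dim(pd$data)[-1]
  out <- pd$data
  for (t in seq_len(n_frames(pd))) {
    if (length(grid) == 2L) {
      out[t, , ] <- gaussian_smooth_array(array(pd$data[t, , ], grid),
                                          sigma_vox)
    } else {
      out[t, , , ] <- gaussian_smooth_array(array(pd$data[t, , , ], grid),
                                            sigma_vox)
    }
  }
  pd$data <- out
  pd
}

#' Flag high-motion frames
#'
#' Thresholds the chosen temporal QC metric: frames with rGS above 10%,
#' rDVARS above 2.0, or GV more than 0.01 mm/s above its first-decile
#' baseline are flagged (defaults; see [denoise_strategy()]). `"none"`
#' flags nothing. The leading `NA` of rDVARS is never flagged.
#'
#' @param qc A [temporal_qc()] table (or compatible data.frame).
#' @param strategy A [denoise_strategy()].
#' @param fs_Hz Frame rate, used to report the retained duration.
#' @return A `scrub_mask`: list with logical `flagged` and
#'   `retained_seconds`.
#' @export
detect_high_motion <- function(qc, strategy, fs_Hz) {
  th <- strategy$thresholds
  flagged <- switch(strategy$scrub_metric,
    none = rep(FALSE, nrow(qc)),
    rgs = qc$rgs_pct > th$rgs,
    rdvars = !is.na(qc$rdvars) & qc$rdvars > th$rdvars,
    gv = {
      d1 <- stats::quantile(qc$gv_mm_s, 0.1, type = 7, names = FALSE)
      qc$gv_mm_s > d1 + th$gv
    })
  structure(list(flagged = flagged,
                 retained_seconds = sum(!flagged) / fs_Hz),
            class = "scrub_mask")
}

#' Replace high-motion frames by the mean of quiet frames
#'
#' The frequency filter requires regular sampling, so flagged frames are not
#' yet deleted but replaced, per voxel, by the average over unflagged
#' frames; they are removed entirely after filtering (see
#' [drop_scrubbed()]).
#'
#' @param pd A [fusi_series()].
#' @param mask A `scrub_mask` from [detect_high_motion()].
#' @return A [fusi_series()] with flagged frames replaced.
#' @export
scrub_replace <- function(pd, mask) {
  fl <- mask$flagged
  if (!any(fl)) return(pd)
  if (all(fl)) stop("all frames flagged: acquisition rejected")
  m <- series_matrix(pd)
  repl <- colMeans(m[!fl, , drop = FALSE])
  m[fl, ] <- rep(repl, each = sum(fl))
  series_from_matrix(pd, m)
}

#' Zero-phase frequency filtering along time
#'
#' High-pass (0.01 Hz) or band-pass (0.01-0.1 Hz) forward-backward
#' Butterworth filtering of every voxel series (order 6 by default), chosen
#' to avoid phase distortion of slow hemodynamic signals.
#'
#' @param x A [fusi_series()], a (time x k) matrix, or a vector.
#' @param kind `"highpass"` or `"bandpass"`.
#' @param fs_Hz Sampling rate; taken from `x` when it is a series.
#' @param order Butterworth order.
#' @param cutoffs_Hz Cutoff(s); default 0.01 for high-pass, c(0.01, 0.1)
#'   for band-pass.
#' @return Filtered object of the same type as the input.
#' @export
frequency_filter <- function(x, kind = c("highpass", "bandpass"),
                             fs_Hz = NULL, order = 6L, cutoffs_Hz = NULL) {
  kind <- match.arg(kind)
  if (inherits(x, "fusi_series")) {
    m <- frequency_filter(series_matrix(x), kind, x$fs_Hz, order, cutoffs_Hz)
    return(series_from_matrix(x, m))
  }
  if (is.null(fs_Hz)) stop("fs_Hz is required for matrix or vector input")
  if (is.null(cutoffs_Hz))
    cutoffs_Hz <- if (kind == "highpass") 0.01 else c(0.01, 0.1)
  filt <- if (kind == "highpass")
    butter_sos(order, cutoffs_Hz, fs_Hz, "high")
  else butter_sos(order, cutoffs_Hz, fs_Hz, "band")
  # pad by 3x the impulse-response scale of the lowest cutoff so the edge
  # transient of the near-DC pole pair stays out of the record
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  pad_target <- ceiling(3 * fs_Hz / min(cutoffs_Hz))
  min_pad <- 3 * (2 * nrow(filt$sos) + 1)
  if (n <= min_pad)
    stop("series too short for zero-phase filtering: need more than ",
         min_pad, " samples, got ", n)
  filtfilt_sos(x, filt, padlen = min(pad_target, n - 1))
}

#' Delete scrubbed frames after filtering
#'
#' Removes the flagged frames entirely and returns the index map from
#' retained position to original frame. Acquisitions retaining less than
#' `min_retained_s` seconds (5 minutes by default) are rejected with a
#' condition of class `fusi_rejection` carrying the retained duration.
#'
#' @param x A [fusi_series()] or (time x k) matrix.
#' @param mask A `scrub_mask`.
#' @param fs_Hz Sampling rate for matrix input.
#' @param min_retained_s Minimum retained duration (s).
#' @return List with `data` (censored series/matrix) and `index_map`
#'   (original frame index of each retained frame).
#' @export
drop_scrubbed <- function(x, mask, fs_Hz = NULL, min_retained_s = 300) {
  fl <- mask$flagged
  if (inherits(x, "fusi_series")) fs_Hz <- x$fs_Hz
  if (is.null(fs_Hz)) stop("fs_Hz is required for matrix input")
  retained_s <- sum(!fl) / fs_Hz
  if (retained_s < min_retained_s) {
    cond <- structure(class = c("fusi_rejection", "error", "condition"),
                      list(message = sprintf(
                        "acquisition rejected: %.1f s retained after scrubbing (< %.0f s)",
                        retained_s, min_retained_s),
                        call = sys.call(-1),
                        retained_seconds = retained_s))
    stop(cond)
  }
  keep <- which(!fl)
  if (inherits(x, "fusi_series")) {
    m <- series_matrix(x)[keep, , drop = FALSE]
    list(data = series_from_matrix(x, m), index_map = keep)
  } else {
    list(data = x[keep, , drop = FALSE], index_map = keep)
  }
}

#' Confound regressors from raw power Doppler
#'
#' Builds the nuisance-regressor matrix. The global signal is the mean over
#' brain voxels. The CompCor variants take the first `n_components`
#' principal components of the (column-mean-centered, unscaled) voxel series
#' in a source mask: the top-5\%-variance voxels (tCompCor), white matter +
#' CSF voxels (aCompCor), a random brain mask of the same cardinality as
#' the WM+CSF mask (random CompCor; drawn once per dataset from `rng_seed`),
#' or the lowest-variance voxels of the same cardinality (low-variance
#' CompCor). Confounds must be estimated from the raw series, before
#' smoothing or any other denoising, to avoid partial-volume leakage into
#' thin anatomical masks. Component signs follow a deterministic
#' convention: the loading with largest magnitude is positive.
#'
#' @param raw_pd The unsmoothed, undenoised power Doppler [fusi_series()].
#' @param method Confound method name (see [denoise_strategy()]).
#' @param masks List with logical arrays `brain` and (for aCompCor-family)
#'   `wm_csf`.
#' @param n_components Number of principal components.
#' @param rng_seed Seed for the random CompCor mask.
#' @param tcompcor_fraction Fraction of highest-variance voxels for
#'   tCompCor.
#' @return A `confound_set`: list with `regressors` (time x k matrix, k = 0
#'   for `"none"`), `method`, and `source_voxels`.
#' @export
compute_confounds <- function(raw_pd, method, masks, n_components = 5L,
                              rng_seed = 1L, tcompcor_fraction = 0.05) {
  nt <- n_frames(raw_pd)
  if (method == "none")
    return(structure(list(regressors = matrix(0, nt, 0), method = method,
                          source_voxels = integer(0)),
                     class = "confound_set"))
  brain <- mask_indices(masks$brain)
  if (!length(brain)) stop("brain mask is empty")
  m <- series_matrix(raw_pd)
  if (method == "global_signal") {
    reg <- matrix(rowMeans(m[, brain, drop = FALSE]), ncol = 1)
    return(structure(list(regressors = reg, method = method,
                          source_voxels = brain),
                     class = "confound_set"))
  }
  src <- switch(method,
    tcompcor = {
      sdv <- apply(m[, brain, drop = FALSE], 2, stats::sd)
      k <- max(1L, floor(tcompcor_fraction * length(brain)))
      brain[order(-sdv, seq_along(sdv))[seq_len(k)]]
    },
    acompcor = {
      wc <- mask_indices(masks$wm_csf)
      if (!length(wc)) stop("aCompCor requires a nonempty wm_csf mask")
      wc
    },
    random_compcor = {
      wc <- mask_indices(masks$wm_csf)
      if (!length(wc)) stop("random CompCor sizes its mask from wm_csf")
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(rng_seed)
      sample(brain, length(wc))
    },
    lowvar_compcor = {
      wc <- mask_indices(masks$wm_csf)
      if (!length(wc)) stop("low-variance CompCor sizes its mask from wm_csf")
      sdv <- apply(m[, brain, drop = FALSE], 2, stats::sd)
      brain[order(sdv, seq_along(sdv))[seq_len(length(wc))]]
    },
    stop("unknown confound method: ", method))
  x <- m[, src, drop = FALSE]
  if (nt <= n_components)
    stop("confound source needs more frames than components")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  structure(list(regressors = scores, method = method, source_voxels = src),
            class = "confound_set")
}

#' Remove confound contributions by least squares
#'
#' Ordinary-least-squares regression of every voxel series on the confound
#' matrix (plus an intercept, always included): returns
#' `X - C %*% beta`. Residuals are orthogonal to every confound column.
#' Linearly dependent confound columns are dropped with a warning.
#'
#' @param x A [fusi_series()] or (time x voxels) matrix.
#' @param confounds A `confound_set` or a plain (time x k) matrix.
#' @return Residual series/matrix of the same type as `x`.
#' @export
regress_confounds <- function(x, confounds) {
  if (inherits(x, "fusi_series")) {
    m <- regress_confounds(series_matrix(x), confounds)
    return(series_from_matrix(x, m))
  }
  C <- if (inherits(confounds, "confound_set")) confounds$regressors
       else confounds
  if (is.null(C) || ncol(C) == 0L) return(x)
  if (nrow(C) != nrow(x))
    stop("confounds and data have different frame counts")
  D <- cbind(intercept = 1, C)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("dropping ", ncol(D) - qrD$rank,
            " linearly dependent confound column(s)")
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
    qrD <- qr(D)
  }
  x - D %*% qr.coef(qrD, x)
}

#' Run the full denoising pipeline on one acquisition
#'
#' Applies, in this fixed order: (1) spatial Gaussian smoothing,
#' (2) scrubbing by replacement of high-motion frames, (3) zero-phase
#' frequency filtering, after which (4) the replaced frames are deleted, and
#' (5) confound regression. Confounds are estimated from the raw series
#' before any of these steps, then passed through the same
#' replace-filter-delete sequence as the data before regression. The order
#' matters: replacing surges before filtering prevents them from ringing
#' through the filter, and deleting them before regression prevents them
#' from leveraging the fit.
#'
#' @param pd_raw Raw power Doppler [fusi_series()] (pre-smoothing).
#' @param vel Matching velocity [fusi_series()] (needed for GV scrubbing).
#' @param strategy A [denoise_strategy()].
#' @param masks List of logical arrays: `brain`, and `wm_csf` for the
#'   aCompCor family.
#' @param rng_seed Seed for the random CompCor mask.
#' @param min_retained_s Scrubbing retention floor in seconds.
#' @return A list: `clean` (censored, denoised [fusi_series()]),
#'   `scrub_mask`, `index_map`, `confounds`, and `tdof_pct` (percent of
#'   frames retained).
#' @export
denoise_pipeline <- function(pd_raw, vel, strategy, masks, rng_seed = 1L,
                             min_retained_s = 300) {
  qc <- temporal_qc(pd_raw, vel, masks$brain)
  mask <- detect_high_motion(qc, strategy, pd_raw$fs_Hz)

  conf <- compute_confounds(pd_raw, strategy$confound_method, masks,
                            strategy$n_components, rng_seed)

  x <- gaussian_smooth(pd_raw, strategy$smoothing_fwhm_mm)
  x <- scrub_replace(x, mask)
  x <- frequency_filter(x, strategy$freq_filter, order = strategy$filter_order)
  dropped <- drop_scrubbed(x, mask, min_retained_s = min_retained_s)
  x <- dropped$data

  C <- conf$regressors
  if (ncol(C) > 0) {
    fl <- mask$flagged
    if (any(fl)) {
      repl <- colMeans(C[!fl, , drop = FALSE])
      C[fl, ] <- rep(repl, each = sum(fl))
    }
    C <- frequency_filter(C, strategy$freq_filter, fs_Hz = pd_raw$fs_Hz,
                          order = strategy$filter_order)
    C <- C[dropped$index_map, , drop = FALSE]
  }
  clean <- regress_confounds(x, C)

  list(clean = clean, scrub_mask = mask, index_map = dropped$index_map,
       confounds = conf,
       tdof_pct = 100 * length(dropped$index_map) / n_frames(pd_raw))
}
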