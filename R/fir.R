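#' Finite-impulse-response design matrix from the global velocity signal
#'
#' Models the power Doppler signal as a linear combination of all delayed
#' copies of the global axial velocity (GV) between `-max_lag_s` and
#' `+max_lag_s`, on the lag grid of the power Doppler sampling rate, plus an
#' intercept and a linear drift. The column for lag `+k` at row `t` holds
#' `gv(t - k)`; samples shifted outside the record are zero-padded and the
#' affected rows are flagged.
#'
#' @param gv Numeric GV series (mm/s).
#' @param fs_Hz Sampling rate of the series (Hz).
#' @param max_lag_s Maximum absolute lag (s).
#' @param drift Include intercept + linear drift columns.
#' @return A `fir_design`: list with `X` (time x columns), `lags_sec`,
#'   `lag_cols` (column indices of the lag regressors), and `padded_rows`.
#' @export
fir_design <- function(gv, fs_Hz, max_lag_s = 12, drift = TRUE) {
  n <- length(gv)
  L <- round(max_lag_s * fs_Hz)
  lags <- -L:L
  X <- matrix(0, nrow = n, ncol = length(lags))
  for (j in seq_along(lags)) {
    k <- lags[j]
    t_src <- seq_len(n) - k
    ok <- t_src >= 1 & t_src <= n
    X[ok, j] <- gv[t_src[ok]]
  }
  padded <- which(seq_len(n) <= L | seq_len(n) > n - L)
  cn <- sprintf("gv_lag_%+d", lags)
  colnames(X) <- cn
  lag_cols <- seq_along(lags)
  if (drift) {
    X <- cbind(X, intercept = 1,
               drift = seq_len(n) / n - 0.5)
  }
  structure(list(X = X, lags_sec = lags / fs_Hz, lag_cols = lag_cols,
                 padded_rows = padded),
            class = "fir_design")
}

#' Subject-level FIR fit
#'
#' Voxelwise ordinary least squares of the power Doppler series on the FIR
#' design. Collinear design columns are dropped with a warning. Plain OLS is
#' used (no prewhitening); the estimates are unbiased under any stationary
#' noise.
#'
#' @param pd A power Doppler [fusi_series()].
#' @param design A [fir_design()] aligned with `pd`.
#' @return A `fir_fit`: list with `beta` (lags x voxels matrix of lag
#'   coefficients), `lags_sec`, and `grid`.
#' @export
fit_fir_subject <- function(pd, design) {
  Y <- series_matrix(pd)
  X <- design$X
  if (nrow(X) != nrow(Y)) stop("design and series have different lengths")
  qrX <- qr(X)
  dropped <- integer(0)
  if (qrX$rank < ncol(X)) {
    dropped <- qrX$pivot[-seq_len(qrX$rank)]
    warning("dropping ", length(dropped), " collinear design column(s)")
    X <- X[, -dropped, drop = FALSE]
    qrX <- qr(X)
  }
  beta_all <- qr.coef(qrX, Y)
  keep <- intersect(design$lag_cols, setdiff(seq_len(ncol(design$X)), dropped))
  # rows of beta_all follow the retained column order
  rn <- colnames(design$X)[keep]
  beta <- beta_all[match(rn, colnames(X)), , drop = FALSE]
  structure(list(beta = beta,
                 lags_sec = design$lags_sec[match(keep, design$lag_cols)],
                 grid = dim(pd$data)[-1]),
            class = "fir_fit")
}

#' Group-level FIR response map
#'
#' One-sample test of the subject-level lag coefficients against zero, per
#' (voxel, lag): `t = mean / (sd / sqrt(n))`, converted to z-scores through
#' the normal quantile of the t cumulative distribution. Optionally averages
#' z over regions of interest to give per-ROI response traces.
#'
#' @param fits List of `fir_fit` objects (>= 2 subjects, common grid and
#'   lags).
#' @param rois Optional named list of voxel-index vectors.
#' @return A `fir_response`: list with `z` (lags x voxels), `lags_sec`,
#'   `roi_traces` (lags x ROIs matrix or `NULL`), `n_subjects`.
#' @export
group_fir <- function(fits, rois = NULL) {
  n <- length(fits)
  if (n < 2L) stop("group-level FIR needs at least 2 subjects")
  lags <- fits[[1]]$lags_sec
  for (f in fits)
    if (!identical(dim(f$beta), dim(fits[[1]]$beta)))
      stop("subjects have mismatched beta stacks")
  stack <- array(unlist(lapply(fits, `[[`, "beta")),
                 dim = c(dim(fits[[1]]$beta), n))
  mu <- apply(stack, c(1, 2), mean)
  sdv <- apply(stack, c(1, 2), stats::sd)
  se <- sdv / sqrt(n)
  tstat <- ifelse(se > 0, mu / se, ifelse(mu == 0, 0, sign(mu) * Inf))
  df <- n - 1
  z <- stats::qnorm(stats::pt(tstat, df, log.p = TRUE), log.p = TRUE)
  # symmetric treatment of the upper tail for numerical accuracy
  pos <- is.finite(tstat) & tstat > 0
  z[pos] <- -stats::qnorm(stats::pt(-tstat[pos], df, log.p = TRUE),
                          log.p = TRUE)
  z[!is.finite(tstat)] <- sign(tstat[!is.finite(tstat)]) * Inf
  traces <- NULL
  if (!is.null(rois)) {
    traces <- vapply(rois, function(idx)
      rowMeans(z[, idx, drop = FALSE]), numeric(length(lags)))
  }
  structure(list(z = z, lags_sec = lags, roi_traces = traces,
                 n_subjects = n),
            class = "fir_response")
}
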