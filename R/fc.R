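#' Seed region specification
#'
#' A spherical seed region given by its center (mm, in the acquisition's
#' voxel coordinate frame: voxel `i` sits at `(i - 1) * voxel_size`) and its
#' radius (0.3 mm by default, the scale of a small subcortical nucleus at
#' 100 um resolution). Voxels belong to the sphere when their center lies
#' within the radius.
#'
#' @param name Seed label (e.g. "S1_left").
#' @param center_mm Numeric vector of coordinates (mm), one per spatial
#'   axis.
#' @param radius_mm Sphere radius (mm).
#' @return A `seed_spec` object.
#' @export
seed_spec <- function(name, center_mm, radius_mm = 0.3) {
  if (radius_mm <= 0) stop("radius_mm must be positive")
  structure(list(name = name, center_mm = as.numeric(center_mm),
                 radius_mm = radius_mm),
            class = "seed_spec")
}

# linear indices of the voxels whose centers fall inside the seed sphere
seed_voxels <- function(seed, grid, voxel_size_mm) {
  if (length(seed$center_mm) != length(grid))
    stop("seed center dimensionality does not match the grid")
  coords <- lapply(seq_along(grid),
                   function(a) ((seq_len(grid[a]) - 1) * voxel_size_mm -
                                  seed$center_mm[a])^2)
  d2 <- Reduce(function(acc, a) outer(acc, coords[[a]], `+`),
               seq_along(grid)[-1], init = coords[[1]])
  idx <- which(as.vector(d2) <= seed$radius_mm^2 + 1e-12)
  if (!length(idx))
    stop("seed sphere `", seed$name, "` contains no voxel centers")
  idx
}

#' Seed signal: mean series over the seed sphere
#'
#' @param clean A denoised [fusi_series()].
#' @param seed A [seed_spec()].
#' @return Numeric vector, one value per frame.
#' @export
seed_signal <- function(clean, seed) {
  idx <- seed_voxels(seed, dim(clean$data)[-1], clean$voxel_size_mm)
  rowMeans(series_matrix(clean)[, idx, drop = FALSE])
}

#' Seed-based correlation map
#'
#' Pearson correlation between the seed signal and every brain voxel of a
#' denoised acquisition. Voxels with zero temporal variance get a zero
#' correlation (flagged in the `zero_variance` attribute) so that thresholding and
#' overlap metrics remain defined everywhere.
#'
#' @param clean A denoised [fusi_series()] (>= 3 frames).
#' @param seed A [seed_spec()].
#' @param brain_mask Logical spatial mask; voxels outside get `NA`.
#' @return A `seed_map`: list with `r` (array over the grid), `seed`,
#'   `n_frames`.
#' @export
seed_map <- function(clean, seed, brain_mask) {
  nt <- n_frames(clean)
  if (nt < 3L) stop("seed_map needs at least 3 frames")
  s <- seed_signal(clean, seed)
  if (stats::sd(s) == 0) stop("degenerate seed: constant seed signal")
  idx <- mask_indices(brain_mask)
  m <- series_matrix(clean)[, idx, drop = FALSE]
  sc <- s - mean(s)
  mc <- sweep(m, 2, colMeans(m))
  denom <- sqrt(sum(sc^2) * colSums(mc^2))
  num <- as.vector(crossprod(mc, sc))
  r <- ifelse(denom > 0, num / denom, 0)
  zero_var <- denom == 0
  grid <- dim(clean$data)[-1]
  vol <- array(NA_real_, grid)
  vol[idx] <- r
  structure(list(r = vol, seed = seed, n_frames = nt,
                 zero_variance = idx[zero_var]),
            class = "seed_map")
}

#' Fisher-z average of seed maps
#'
#' Correlations are transformed to Fisher z (`atanh`), averaged, and
#' back-transformed (`tanh`), the unbiased way to average correlation maps
#' across acquisitions or subjects. Values at +/-1 are clipped to
#' +/-(1 - 1e-7) before the transform.
#'
#' @param maps Nonempty list of `seed_map` objects on a common grid.
#' @return A `seed_map` holding the group-average correlations.
#' @export
average_maps_fisher <- function(maps) {
  if (!length(maps)) stop("need at least one map")
  zs <- lapply(maps, function(m) atanh(pmin(pmax(m$r, -(1 - 1e-7)),
                                            1 - 1e-7)))
  zbar <- Reduce(`+`, zs) / length(zs)
  out <- maps[[1]]
  out$r <- tanh(zbar)
  out$n_frames <- NA_integer_
  out
}

#' Top-fraction threshold of a correlation map
#'
#' Marks the `floor(fraction * N_brain)` brain voxels with the highest
#' absolute (default) or signed correlation. Ties are broken by voxel linear
#' index, so the mask is deterministic.
#'
#' @param map A `seed_map` (or a plain array of correlations).
#' @param brain_mask Logical spatial mask.
#' @param fraction Fraction of brain voxels to keep, in (0, 1].
#' @param by_absolute Rank by `|r|` (the benchmark convention) or by signed
#'   `r` (the display convention).
#' @return Logical array over the grid.
#' @export
threshold_top_fraction <- function(map, brain_mask, fraction = 0.10,
                                   by_absolute = TRUE) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  r <- if (inherits(map, "seed_map")) map$r else map
  idx <- mask_indices(brain_mask)
  if (!length(idx)) stop("brain mask is empty")
  vals <- r[idx]
  key <- if (by_absolute) abs(vals) else vals
  k <- floor(fraction * length(idx))
  out <- array(FALSE, dim = dim(r))
  if (k >= 1L) {
    top <- order(-key, idx)[seq_len(k)]
    out[idx[top]] <- TRUE
  }
  out
}

#' Seed maps for a set of seeds
#'
#' @param clean A denoised [fusi_series()].
#' @param seeds List of [seed_spec()] objects.
#' @param brain_mask Logical spatial mask.
#' @return Named list of `seed_map` objects.
#' @export
seed_maps <- function(clean, seeds, brain_mask) {
  out <- lapply(seeds, seed_map, clean = clean, brain_mask = brain_mask)
  names(out) <- vapply(seeds, function(s) s$name, "")
  out
}
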