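#' Write / read a time series volume as NIfTI
#'
#' Series are stored in the conventional neuroimaging layout: spatial axes
#' first, time last, voxel size in mm in the header `pixdim`, and the frame
#' period as the temporal pixdim. Internally the package keeps time first;
#' the writer/reader transpose.
#'
#' @param x A [fusi_series()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_series_nifti`: the path, invisibly.
#' @export
write_series_nifti <- function(x, path) {
  d <- dim(x$data)
  nd <- length(d) - 1L
  arr <- aperm(x$data, c(seq_len(nd) + 1L, 1L))
  if (nd == 2L) {  # promote 2D+t to x,y,1,t so time sits on the 4th axis
    arr <- array(arr, dim = c(d[2], d[3], 1L, d[1]))
    pix <- c(x$voxel_size_mm, x$voxel_size_mm, x$voxel_size_mm, 1 / x$fs_Hz)
  } else {
    pix <- c(rep(x$voxel_size_mm, 3), 1 / x$fs_Hz)
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pix
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_series_nifti
#' @param kind `"pd"` or `"velocity"` for the reconstructed series.
#' @export
read_series_nifti <- function(path, kind = c("pd", "velocity")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  pix <- RNifti::pixdim(img)
  voxel <- pix[1]
  tr <- pix[length(d)]
  if (length(d) == 4L && d[3] == 1L) {  # stored 2D+t
    arr <- array(arr, dim = c(d[1], d[2], d[4]))
    d <- dim(arr)
  }
  nd <- length(d) - 1L
  data <- aperm(arr, c(nd + 1L, seq_len(nd)))
  fusi_series(data, fs_Hz = 1 / tr, voxel_size_mm = voxel, kind = kind)
}

#' Write / read a spatial mask as NIfTI
#'
#' @param mask Logical array (2D or 3D).
#' @param path Output path.
#' @param voxel_size_mm Voxel spacing (mm).
#' @export
write_mask_nifti <- function(mask, path, voxel_size_mm = 0.1) {
  d <- dim(mask)
  arr <- array(as.integer(mask), dim = if (length(d) == 2L) c(d, 1L) else d)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) == 3L && d[3] == 1L) arr <- array(arr, dim = d[1:2])
  arr > 0
}

#' On-disk I/Q container
#'
#' Stores an acquisition's beamformed I/Q blocks as a pair of NIfTI volumes
#' (real and imaginary parts, spatial axes first, all frames concatenated
#' along time) plus a JSON sidecar with the acquisition parameters
#' (`f_pulse_Hz`, `c_m_per_s`, `f_iq_Hz`, `voxel_size_mm`, `block_len`,
#' `n_blocks`).
#'
#' @param blocks List of [iq_block()] objects (equal shape).
#' @param stem Path stem; writes `<stem>_real.nii.gz`, `<stem>_imag.nii.gz`,
#'   `<stem>.json`.
#' @return `write_iq_container`: the sidecar path, invisibly.
#' @export
write_iq_container <- function(blocks, stem) {
  if (!length(blocks)) stop("need at least one block")
  b1 <- blocks[[1]]
  L <- block_len(b1); grid <- grid_shape(b1)
  nd <- length(grid)
  all_s <- array(unlist(lapply(blocks, function(b)
    aperm(b$samples, c(seq_len(nd) + 1L, 1L)))),
    dim = c(grid, L * length(blocks)))
  pack <- function(part, suffix) {
    arr <- if (nd == 2L)
      array(part, dim = c(grid[1], grid[2], 1L, dim(all_s)[nd + 1L]))
    else part
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(rep(b1$voxel_size_mm, 3), 1 / b1$f_iq_Hz)
    RNifti::writeNifti(img, paste0(stem, suffix))
  }
  pack(Re(all_s), "_real.nii.gz")
  pack(Im(all_s), "_imag.nii.gz")
  side <- list(f_pulse_Hz = b1$f_pulse_Hz, c_m_per_s = b1$c_m_per_s,
               f_iq_Hz = b1$f_iq_Hz, voxel_size_mm = b1$voxel_size_mm,
               block_len = L, n_blocks = length(blocks),
               grid_shape = as.integer(grid))
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(stem, ".json"))
}

#' @rdname write_iq_container
#' @export
read_iq_container <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  re <- as.array(RNifti::readNifti(paste0(stem, "_real.nii.gz")))
  im <- as.array(RNifti::readNifti(paste0(stem, "_imag.nii.gz")))
  grid <- side$grid_shape
  nd <- length(grid)
  nt <- side$block_len * side$n_blocks
  re <- array(re, dim = c(grid, nt))
  im <- array(im, dim = c(grid, nt))
  s <- complex(real = re, imaginary = im)
  dim(s) <- c(grid, nt)
  s <- aperm(s, c(nd + 1L, seq_len(nd)))
  lapply(seq_len(side$n_blocks), function(b) {
    rows <- (b - 1) * side$block_len + seq_len(side$block_len)
    samp <- if (nd == 2L) s[rows, , , drop = FALSE]
            else s[rows, , , , drop = FALSE]
    iq_block(array(samp, dim = c(side$block_len, grid)),
             f_pulse_Hz = side$f_pulse_Hz, c_m_per_s = side$c_m_per_s,
             f_iq_Hz = side$f_iq_Hz, voxel_size_mm = side$voxel_size_mm)
  })
}

#' TSV writers (BIDS-derivatives dialect)
#'
#' Tab-separated, UTF-8, header row mandatory, missing values written as
#' `n/a`.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "n/a",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, na.strings = "n/a",
                    fileEncoding = "UTF-8")
}

#' Write a confound set as TSV
#'
#' One column per regressor, named `<method>_01`, `<method>_02`, ...
#'
#' @param confounds A `confound_set`.
#' @param path Output path.
#' @export
write_confounds_tsv <- function(confounds, path) {
  k <- ncol(confounds$regressors)
  df <- as.data.frame(confounds$regressors)
  names(df) <- if (k) sprintf("%s_%02d", confounds$method, seq_len(k))
               else character(0)
  write_tsv(df, path)
}

#' Write a scrub mask as TSV (one 0/1 row per frame)
#'
#' @param mask A `scrub_mask`.
#' @param path Output path.
#' @export
write_scrub_tsv <- function(mask, path) {
  write_tsv(data.frame(frame = seq_along(mask$flagged),
                       flagged = as.integer(mask$flagged)), path)
}
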