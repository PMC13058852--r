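#' Load and validate a pipeline configuration
#'
#' Reads a YAML or JSON configuration describing one end-to-end run and
#' resolves all defaults. Unspecified denoising parameters default to the
#' recommended optimized paradigm: constant-energy SVD_40 with brain mask,
#' rDVARS scrubbing, 0.01 Hz high-pass, aCompCor. Strategy invariants are
#' enforced (notably the forbidden constant-energy + rGS combination).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `pipeline_config`: list with `inputs` (paths), `strategy` (a
#'   [denoise_strategy()]), `seeds`, `rng_seed`, `out_dir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be YAML or JSON, got .", ext)
  as_pipeline_config(raw, dirname(path))
}

as_pipeline_config <- function(raw, base_dir = ".") {
  need <- function(x, field) {
    if (is.null(x)) stop("config is missing required field `", field, "`")
    x
  }
  inputs <- need(raw$inputs, "inputs")
  strat_raw <- raw$strategy
  clut <- clutter_filter_spec(
    method = strat_raw$clutter$method %||% "constant_energy",
    T_count = strat_raw$clutter$T_count %||% 40L,
    use_brain_mask = strat_raw$clutter$use_brain_mask %||% TRUE)
  strategy <- denoise_strategy(
    clutter = clut,
    scrub_metric = strat_raw$scrub_metric %||% "rdvars",
    freq_filter = strat_raw$freq_filter %||% "highpass",
    confound_method = strat_raw$confound_method %||% "acompcor",
    n_components = strat_raw$n_components %||% 5L,
    smoothing_fwhm_mm = strat_raw$smoothing_fwhm_mm %||% 0.3)
  seeds <- lapply(raw$seeds, function(s)
    seed_spec(need(s$name, "seeds$name"),
              need(s$center_mm, "seeds$center_mm"),
              s$radius_mm %||% 0.3))
  structure(list(inputs = inputs, strategy = strategy, seeds = seeds,
                 rng_seed = raw$rng_seed %||% 1L,
                 out_dir = raw$out_dir %||% file.path(base_dir, "out"),
                 min_retained_s = raw$min_retained_s %||% 300),
            class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a pipeline configuration
#'
#' Writes the configuration back to YAML or JSON such that
#' [load_config()] round-trips it losslessly.
#'
#' @param config A `pipeline_config`.
#' @param path Output path (`.yaml` or `.json`).
#' @export
save_config <- function(config, path) {
  s <- config$strategy
  raw <- list(
    inputs = config$inputs,
    strategy = list(
      clutter = list(method = s$clutter$method, T_count = s$clutter$T_count,
                     use_brain_mask = s$clutter$use_brain_mask),
      scrub_metric = s$scrub_metric, freq_filter = s$freq_filter,
      confound_method = s$confound_method, n_components = s$n_components,
      smoothing_fwhm_mm = s$smoothing_fwhm_mm),
    seeds = lapply(config$seeds, function(sd)
      list(name = sd$name, center_mm = sd$center_mm,
           radius_mm = sd$radius_mm)),
    rng_seed = config$rng_seed, out_dir = config$out_dir,
    min_retained_s = config$min_retained_s)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(raw, path)
  else jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the end-to-end pipeline
#'
#' Executes velocity estimation, clutter filtering / power Doppler
#' integration (when the input is an I/Q container), quality control,
#' denoising and seed-based connectivity, writing every artifact under
#' `config$out_dir` and a JSON manifest listing each file with its MD5
#' checksum. An acquisition rejected by the 5-minute scrubbing rule yields
#' `status = "rejected"` in the manifest rather than an error.
#'
#' @param config A `pipeline_config` (see [load_config()]); its `inputs`
#'   must name either `iq_stem` (an I/Q container stem) or both `pd` and
#'   `vel` NIfTI paths, plus `brain_mask` and optionally `wm_csf_mask`.
#' @return The manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  art <- character(0)
  add <- function(p) { art[[length(art) + 1L]] <<- p; p }

  if (!is.null(config$inputs$iq_stem)) {
    blocks <- read_iq_container(config$inputs$iq_stem)
    vel <- velocity_series(blocks)
    mask <- if (!is.null(config$inputs$brain_mask))
      read_mask_nifti(config$inputs$brain_mask)
    else array(TRUE, dim = grid_shape(blocks[[1]]))
    pd <- iq_to_power_doppler(blocks, config$strategy$clutter, mask)$pd
  } else {
    pd <- read_series_nifti(config$inputs$pd, "pd")
    vel <- read_series_nifti(config$inputs$vel, "velocity")
    mask <- if (!is.null(config$inputs$brain_mask))
      read_mask_nifti(config$inputs$brain_mask)
    else array(TRUE, dim = dim(pd$data)[-1])
  }
  masks <- list(brain = mask)
  if (!is.null(config$inputs$wm_csf_mask))
    masks$wm_csf <- read_mask_nifti(config$inputs$wm_csf_mask)

  qc <- temporal_qc(pd, vel, masks$brain)
  add(write_tsv(qc, file.path(config$out_dir, "qc.tsv")))
  add(write_series_nifti(vel, file.path(config$out_dir, "velocity.nii.gz")))
  add(write_series_nifti(pd, file.path(config$out_dir, "pd.nii.gz")))

  status <- "ok"
  retained <- NA_real_
  res <- tryCatch(
    denoise_pipeline(pd, vel, config$strategy, masks,
                     rng_seed = config$rng_seed,
                     min_retained_s = config$min_retained_s),
    fusi_rejection = function(e) {
      status <<- "rejected"
      retained <<- e$retained_seconds
      NULL
    })

  if (!is.null(res)) {
    retained <- res$scrub_mask$retained_seconds
    add(write_series_nifti(res$clean,
                           file.path(config$out_dir, "clean.nii.gz")))
    add(write_scrub_tsv(res$scrub_mask,
                        file.path(config$out_dir, "scrub.tsv")))
    add(write_confounds_tsv(res$confounds,
                            file.path(config$out_dir, "confounds.tsv")))
    for (sd_ in config$seeds) {
      m <- seed_map(res$clean, sd_, masks$brain)
      vol <- fusi_series(array(ifelse(is.na(m$r), 0, m$r),
                               dim = c(1, dim(m$r))),
                         fs_Hz = 1, voxel_size_mm = res$clean$voxel_size_mm)
      p <- file.path(config$out_dir,
                     paste0("seedmap_", sd_$name, ".nii.gz"))
      add(write_series_nifti(vol, p))
      jsonlite::write_json(list(seed = sd_$name, center_mm = sd_$center_mm,
                                radius_mm = sd_$radius_mm,
                                n_frames = m$n_frames),
                           sub("\\.nii\\.gz$", ".json", p),
                           auto_unbox = TRUE, digits = NA)
      add(sub("\\.nii\\.gz$", ".json", p))
    }
  }

  manifest <- list(
    status = status,
    retained_seconds = retained,
    tdof_pct = if (!is.null(res)) res$tdof_pct else NA_real_,
    strategy = list(clutter = config$strategy$clutter$method,
                    T_count = config$strategy$clutter$T_count,
                    scrub = config$strategy$scrub_metric,
                    freq = config$strategy$freq_filter,
                    confound = config$strategy$confound_method),
    artifacts = lapply(unlist(art), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
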