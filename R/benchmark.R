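#' Factorial grid of denoising strategies
#'
#' The benchmark crosses 3 clutter methods x 3 static thresholds x 2 mask
#' options x 4 scrubbing options x 2 frequency filters x 6 confound methods
#' (864 combinations). Combinations of the constant-energy clutter filter
#' with rGS scrubbing are excluded a priori (the adaptive filter flattens
#' the global signal), leaving 792 unique strategies. Dropping the scrubbing
#' factor altogether (as the motion-robustness metric does) leaves 216.
#'
#' @param clutter_methods,thresholds_T,mask_options,scrub_options,freq_options,confound_options
#'   Factor levels; defaults are the full benchmark grid.
#' @return A `strategy_grid` object.
#' @export
strategy_grid <- function(clutter_methods = c("static", "static_highpass",
                                              "constant_energy"),
                          thresholds_T = c(20L, 40L, 60L),
                          mask_options = c(FALSE, TRUE),
                          scrub_options = c("rgs", "rdvars", "gv", "none"),
                          freq_options = c("highpass", "bandpass"),
                          confound_options = c("none", "global_signal",
                                               "tcompcor", "acompcor",
                                               "random_compcor",
                                               "lowvar_compcor")) {
  structure(list(clutter_methods = clutter_methods,
                 thresholds_T = thresholds_T, mask_options = mask_options,
                 scrub_options = scrub_options, freq_options = freq_options,
                 confound_options = confound_options),
            class = "strategy_grid")
}

#' Enumerate denoising strategies
#'
#' Expands the factorial grid in deterministic lexicographic order (clutter
#' method, threshold, mask, scrubbing, frequency filter, confound method,
#' with the last factor varying fastest).
#'
#' @param grid A [strategy_grid()].
#' @param mode `"full"` (all combinations), `"post_exclusion"` (minus the
#'   constant-energy x rGS pairs), or `"no_scrubbing"` (scrubbing factor
#'   removed entirely).
#' @return List of [denoise_strategy()] objects.
#' @export
enumerate_strategies <- function(grid = strategy_grid(),
                                 mode = c("post_exclusion", "full",
                                          "no_scrubbing")) {
  mode <- match.arg(mode)
  scrubs <- if (mode == "no_scrubbing") "none" else grid$scrub_options
  combos <- expand.grid(confound = grid$confound_options,
                        freq = grid$freq_options,
                        scrub = scrubs,
                        mask = grid$mask_options,
                        T_count = grid$thresholds_T,
                        clutter = grid$clutter_methods,
                        stringsAsFactors = FALSE)
  if (mode == "post_exclusion")
    combos <- combos[!(combos$clutter == "constant_energy" &
                         combos$scrub == "rgs"), , drop = FALSE]
  lapply(seq_len(nrow(combos)), function(i) {
    co <- combos[i, ]
    spec <- clutter_filter_spec(co$clutter, T_count = co$T_count,
                                use_brain_mask = co$mask)
    if (mode == "full" && co$clutter == "constant_energy" &&
          co$scrub == "rgs") {
      # the full grid counts the a-priori-excluded pairs; build them without
      # the validity check so they can be enumerated (but not run)
      s <- denoise_strategy(spec, scrub_metric = "none",
                            freq_filter = co$freq,
                            confound_method = co$confound)
      s$scrub_metric <- "rgs"
      s
    } else {
      denoise_strategy(clutter = spec, scrub_metric = co$scrub,
                       freq_filter = co$freq, confound_method = co$confound)
    }
  })
}

#' Dice overlap of two binary masks
#'
#' `2 |A intersect B| / (|A| + |B|)`, ranging from 0 (no overlap) to 1
#' (perfect overlap). Two empty masks are defined to have Dice 1.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks have different shapes")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0) return(1)
  2 * sum(a & b) / (na + nb)
}

# subject-then-group aggregation of a per-acquisition statistic
aggregate_by_subject <- function(values, subjects) {
  per_subj <- tapply(values, subjects, mean)
  c(mean = mean(per_subj), sd = stats::sd(per_subj))
}

#' Motion-robustness metric
#'
#' How susceptible a (clutter, frequency, confound) combination is to motion
#' artifacts: the mean squared error, over brain voxels and seeds, between
#' seed-based maps computed without scrubbing and with GV-based scrubbing.
#' If removing motion frames does not change the maps, the pipeline was
#' robust. Per-acquisition MSEs are averaged within subject, then across
#' subjects; the sd is across subjects.
#'
#' @param maps_no_scrub,maps_gv_scrub Lists (one element per acquisition) of
#'   lists of `seed_map` objects, paired.
#' @param subjects Subject label per acquisition.
#' @param brain_mask Logical spatial mask.
#' @return Named vector `c(mean, sd)` of the MSE across subjects.
#' @export
motion_robustness <- function(maps_no_scrub, maps_gv_scrub, subjects,
                              brain_mask) {
  if (length(maps_no_scrub) != length(maps_gv_scrub))
    stop("unpaired acquisitions between the two map sets")
  idx <- mask_indices(brain_mask)
  mse <- vapply(seq_along(maps_no_scrub), function(i) {
    a <- maps_no_scrub[[i]]; b <- maps_gv_scrub[[i]]
    if (length(a) != length(b)) stop("unpaired seeds in acquisition ", i)
    diffs <- vapply(seq_along(a),
                    function(s) mean((a[[s]]$r[idx] - b[[s]]$r[idx])^2),
                    numeric(1))
    mean(diffs)
  }, numeric(1))
  aggregate_by_subject(mse, subjects)
}

#' Functional-connectivity similarity metric
#'
#' How well a strategy preserves group-level connectivity: each subject
#' seed map and the corresponding ground-truth group map (computed with the
#' standard strategy and Fisher-averaged across subjects) are thresholded to
#' their top 10\% of brain voxels by absolute correlation, and their overlap
#' is scored with the Dice coefficient. Dice values are averaged over seeds
#' per acquisition, within subject, then across subjects.
#'
#' @param subject_maps List (per acquisition) of named lists of `seed_map`s.
#' @param gt_maps Named list of ground-truth group `seed_map`s (same seed
#'   names).
#' @param subjects Subject label per acquisition.
#' @param brain_mask Logical spatial mask.
#' @param fraction Threshold fraction (0.10).
#' @return Named vector `c(mean, sd)` of the Dice coefficient across
#'   subjects.
#' @export
fc_similarity <- function(subject_maps, gt_maps, subjects, brain_mask,
                          fraction = 0.10) {
  if (!length(gt_maps)) stop("missing ground-truth maps")
  gt_masks <- lapply(gt_maps, threshold_top_fraction, brain_mask = brain_mask,
                     fraction = fraction, by_absolute = TRUE)
  dice_acq <- vapply(subject_maps, function(maps) {
    ds <- vapply(names(gt_masks), function(nm) {
      if (is.null(maps[[nm]])) stop("acquisition is missing seed ", nm)
      dice(threshold_top_fraction(maps[[nm]], brain_mask, fraction, TRUE),
           gt_masks[[nm]])
    }, numeric(1))
    mean(ds)
  }, numeric(1))
  aggregate_by_subject(dice_acq, subjects)
}

#' Score one strategy on a power-Doppler-level dataset
#'
#' Runs the denoising pipeline for every acquisition of a dataset under a
#' strategy and computes both benchmark metrics. The motion-robustness
#' metric compares the strategy without scrubbing against the same strategy
#' with GV scrubbing; the similarity metric uses the strategy as given
#' against the supplied ground-truth group maps. Acquisitions rejected by
#' the 5-minute retention rule are skipped and counted; a strategy retaining
#' fewer than two thirds of the subjects is flagged invalid rather than
#' silently dropped.
#'
#' @param dataset List of acquisitions, each a list with `pd`, `vel`,
#'   `subject`.
#' @param strategy A [denoise_strategy()].
#' @param gt_maps Ground-truth group maps (see [fc_similarity()]).
#' @param seeds List of [seed_spec()] objects.
#' @param masks List of logical arrays `brain` (and `wm_csf`).
#' @param rng_seed Seed forwarded to the confound step.
#' @param min_retained_s Scrubbing retention floor (s).
#' @return One-row data.frame: strategy id, `mse_mean`, `mse_sd`,
#'   `dice_mean`, `dice_sd`, `retained_subject_fraction`, `tdof_pct`,
#'   `valid`.
#' @export
score_strategy <- function(dataset, strategy, gt_maps, seeds, masks,
                           rng_seed = 1L, min_retained_s = 300) {
  run_maps <- function(strat) {
    lapply(dataset, function(acq) {
      res <- tryCatch(
        denoise_pipeline(acq$pd, acq$vel, strat, masks, rng_seed,
                         min_retained_s),
        fusi_rejection = function(e) NULL)
      if (is.null(res)) return(NULL)
      list(maps = seed_maps(res$clean, seeds, masks$brain),
           tdof = res$tdof_pct)
    })
  }
  strat_noscrub <- strategy
  strat_noscrub$scrub_metric <- "none"
  strat_gv <- strategy
  strat_gv$scrub_metric <- "gv"

  res_main <- run_maps(strategy)
  res_ns <- run_maps(strat_noscrub)
  res_gv <- run_maps(strat_gv)

  subjects <- vapply(dataset, function(a) as.character(a$subject), "")
  ok_pair <- !vapply(res_ns, is.null, TRUE) & !vapply(res_gv, is.null, TRUE)
  mse <- if (any(ok_pair)) {
    motion_robustness(lapply(res_ns[ok_pair], `[[`, "maps"),
                      lapply(res_gv[ok_pair], `[[`, "maps"),
                      subjects[ok_pair], masks$brain)
  } else c(mean = NA_real_, sd = NA_real_)

  ok_main <- !vapply(res_main, is.null, TRUE)
  dice_stat <- if (any(ok_main)) {
    fc_similarity(lapply(res_main[ok_main], `[[`, "maps"),
                  gt_maps, subjects[ok_main], masks$brain)
  } else c(mean = NA_real_, sd = NA_real_)

  retained_frac <- length(unique(subjects[ok_main])) /
    length(unique(subjects))
  tdof <- if (any(ok_main))
    mean(vapply(res_main[ok_main], `[[`, numeric(1), "tdof")) else NA_real_

  data.frame(clutter = strategy$clutter$method,
             T_count = strategy$clutter$T_count,
             brain_mask = strategy$clutter$use_brain_mask,
             scrub = strategy$scrub_metric, freq = strategy$freq_filter,
             confound = strategy$confound_method,
             mse_mean = unname(mse["mean"]), mse_sd = unname(mse["sd"]),
             dice_mean = unname(dice_stat["mean"]),
             dice_sd = unname(dice_stat["sd"]),
             retained_subject_fraction = retained_frac,
             tdof_pct = tdof,
             valid = retained_frac >= 2 / 3,
             stringsAsFactors = FALSE)
}

#' Group ground-truth maps under the standard strategy
#'
#' Convenience wrapper computing the "standard practice" reference: every
#' acquisition denoised with the standard strategy (static SVD_60 without
#' brain mask, rGS scrubbing at 10\%, 0.01-0.1 Hz band-pass, global-signal
#' regression), seed maps Fisher-averaged across acquisitions.
#'
#' @inheritParams score_strategy
#' @param strategy The reference strategy; defaults to
#'   [standard_strategy()].
#' @return Named list of group `seed_map`s.
#' @export
ground_truth_maps <- function(dataset, seeds, masks,
                              strategy = standard_strategy(),
                              rng_seed = 1L, min_retained_s = 300) {
  all_maps <- lapply(dataset, function(acq) {
    res <- tryCatch(
      denoise_pipeline(acq$pd, acq$vel, strategy, masks, rng_seed,
                       min_retained_s),
      fusi_rejection = function(e) NULL)
    if (is.null(res)) return(NULL)
    seed_maps(res$clean, seeds, masks$brain)
  })
  all_maps <- all_maps[!vapply(all_maps, is.null, TRUE)]
  if (!length(all_maps)) stop("no acquisition survived the standard strategy")
  out <- lapply(names(all_maps[[1]]), function(nm)
    average_maps_fisher(lapply(all_maps, `[[`, nm)))
  names(out) <- names(all_maps[[1]])
  out
}

#' Reference denoising strategies
#'
#' `standard_strategy()` is the common-practice reference used as ground
#' truth for the similarity metric: static SVD_60, no brain mask, rGS
#' scrubbing, 0.01-0.1 Hz band-pass, global-signal regression.
#' `paradigm1_strategy()` is the recommended optimized paradigm:
#' constant-energy SVD_40 with brain mask, rDVARS scrubbing, 0.01 Hz
#' high-pass, aCompCor.
#'
#' @return A [denoise_strategy()].
#' @export
standard_strategy <- function() {
  denoise_strategy(clutter = clutter_filter_spec("static", 60L,
                                                 use_brain_mask = FALSE),
                   scrub_metric = "rgs", freq_filter = "bandpass",
                   confound_method = "global_signal")
}

#' @rdname standard_strategy
#' @export
paradigm1_strategy <- function() {
  denoise_strategy(clutter = clutter_filter_spec("constant_energy", 40L,
                                                 use_brain_mask = TRUE),
                   scrub_metric = "rdvars", freq_filter = "highpass",
                   confound_method = "acompcor")
}

#' Run the benchmark over a list of strategies
#'
#' @inheritParams score_strategy
#' @param strategies List of [denoise_strategy()] objects.
#' @return A data.frame with one row per strategy (see [score_strategy()]).
#' @export
run_benchmark <- function(dataset, strategies, gt_maps, seeds, masks,
                          rng_seed = 1L, min_retained_s = 300) {
  rows <- lapply(strategies, function(s)
    score_strategy(dataset, s, gt_maps, seeds, masks, rng_seed,
                   min_retained_s))
  do.call(rbind, rows)
}
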