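test_that("the forbidden strategy combination is rejected", {
  expect_error(denoise_strategy(clutter_filter_spec("constant_energy", 40L),
                                scrub_metric = "rgs"),
               "forbidden")
  # all other clutter x scrub pairs construct fine
  for (m in c("static", "static_highpass"))
    for (s in c("rgs", "rdvars", "gv", "none"))
      expect_s3_class(denoise_strategy(clutter_filter_spec(m, 20L),
                                       scrub_metric = s), "denoise_strategy")
})

test_that("Gaussian smoothing of a series is mass-preserving and optional", {
  grid <- c(9, 9)
  m <- matrix(0, 3, 81)
  m[, 41] <- 1  # delta at the center voxel
  pd <- pd_from_matrix(m, grid)
  expect_identical(gaussian_smooth(pd, 0), pd)
  sm <- gaussian_smooth(pd, 0.3)
  expect_equal(sum(sm$data[1, , ]), 1, tolerance = 1e-6)
  expect_error(gaussian_smooth(pd, -1), "nonnegative")
})

test_that("high-motion detection applies the stated thresholds", {
  qc <- data.frame(frame = 1:10, t_sec = (0:9) / 2.5,
                   rgs_pct = c(rep(1, 9), 20),
                   gv_mm_s = c(0.02, 0.05, rep(0.02, 8)),
                   rdvars = c(NA, rep(1, 9)))
  st_gv <- denoise_strategy(scrub_metric = "gv")
  m <- detect_high_motion(qc, st_gv, 2.5)
  expect_identical(which(m$flagged), 2L)  # 0.05 > D1(0.02) + 0.01
  st_rd <- denoise_strategy(scrub_metric = "rdvars")
  expect_false(any(detect_high_motion(qc, st_rd, 2.5)$flagged))
  st_rgs <- denoise_strategy(scrub_metric = "rgs")
  expect_identical(which(detect_high_motion(qc, st_rgs, 2.5)$flagged), 10L)
  st_none <- denoise_strategy(scrub_metric = "none")
  mn <- detect_high_motion(qc, st_none, 2.5)
  expect_false(any(mn$flagged))
  expect_equal(mn$retained_seconds, 10 / 2.5)
})

test_that("scrub replacement substitutes the mean of quiet frames", {
  grid <- c(1, 1)
  pd <- pd_from_matrix(matrix(c(1, 10, 2), 3, 1), grid)
  mask <- structure(list(flagged = c(FALSE, TRUE, FALSE),
                         retained_seconds = 2 / 2.5), class = "scrub_mask")
  out <- scrub_replace(pd, mask)
  expect_equal(as.vector(out$data), c(1, 1.5, 2))
  empty <- structure(list(flagged = rep(FALSE, 3)), class = "scrub_mask")
  expect_identical(scrub_replace(pd, empty), pd)
  allf <- structure(list(flagged = rep(TRUE, 3)), class = "scrub_mask")
  expect_error(scrub_replace(pd, allf), "rejected")
})

test_that("dropping scrubbed frames enforces the five-minute retention rule", {
  grid <- c(1, 1)
  pd <- pd_from_matrix(matrix(rnorm(100), 100, 1), grid)
  empty <- structure(list(flagged = rep(FALSE, 100)), class = "scrub_mask")
  out <- drop_scrubbed(pd, empty, min_retained_s = 0)
  expect_identical(out$index_map, 1:100)
  fl <- rep(FALSE, 100); fl[1:10] <- TRUE
  out2 <- drop_scrubbed(pd, structure(list(flagged = fl),
                                      class = "scrub_mask"),
                        min_retained_s = 0)
  expect_equal(fusiclean:::n_frames(out2$data), 90)
  # 3000 frames at 2.5 Hz with 2260 flagged: 296 s retained -> rejected
  pd3 <- pd_from_matrix(matrix(0, 3000, 1), grid)
  fl3 <- rep(FALSE, 3000); fl3[seq_len(2260)] <- TRUE
  err <- tryCatch(drop_scrubbed(pd3, structure(list(flagged = fl3),
                                               class = "scrub_mask")),
                  fusi_rejection = function(e) e)
  expect_s3_class(err, "fusi_rejection")
  expect_equal(err$retained_seconds, 296)
})

test_that("confound computation matches its definitions", {
  grid <- c(4, 4)
  set.seed(8)
  nt <- 200
  # rank-1 data: latent signal times a spatial map, plus tiny noise
  lat <- sin(2 * pi * (1:nt) / 50)
  map <- runif(16, 0.5, 1.5)
  m <- 100 + outer(lat, map) + matrix(rnorm(nt * 16, sd = 1e-3), nt, 16)
  pd <- pd_from_matrix(m, grid)
  masks <- list(brain = full_mask(grid),
                wm_csf = array(rep(c(TRUE, FALSE), c(4, 12)), grid))
  cf <- compute_confounds(pd, "acompcor", masks, n_components = 2)
  expect_gt(abs(cor(cf$regressors[, 1], lat)), 0.999)

  expect_equal(ncol(compute_confounds(pd, "none", masks)$regressors), 0)

  # global signal on a spatially uniform volume equals the frame value
  u <- pd_from_matrix(matrix(rep(1:10, 16), 10, 16), grid)
  g <- compute_confounds(u, "global_signal", masks)
  expect_equal(as.vector(g$regressors), as.numeric(1:10))

  # mask cardinalities: random and low-variance match wm_csf; tcompcor 5%
  for (meth in c("random_compcor", "lowvar_compcor"))
    expect_length(compute_confounds(pd, meth, masks)$source_voxels, 4)
  tc <- compute_confounds(pd, "tcompcor", masks, tcompcor_fraction = 0.25)
  expect_length(tc$source_voxels, 4)
  # random mask is reproducible from the seed
  r1 <- compute_confounds(pd, "random_compcor", masks, rng_seed = 5)
  r2 <- compute_confounds(pd, "random_compcor", masks, rng_seed = 5)
  expect_identical(r1$source_voxels, r2$source_voxels)
})

test_that("confound regression matches the normal-equations oracle", {
  set.seed(19)
  nt <- 120
  X <- matrix(rnorm(nt * 10), nt, 10)
  C <- matrix(rnorm(nt * 3), nt, 3)
  got <- regress_confounds(X, C)
  D <- cbind(1, C)
  beta <- solve(t(D) %*% D, t(D) %*% X)
  expect_equal(got, X - D %*% beta, tolerance = 1e-8)
  # residuals orthogonal to every confound column
  expect_lt(max(abs(t(C) %*% got)) / sqrt(sum(X^2)), 1e-8)
  # perfect fit annihilates the data
  Xfit <- C %*% matrix(rnorm(30), 3, 10)
  expect_lt(max(abs(regress_confounds(Xfit, C))), 1e-8)
  # k = 0 is the identity
  expect_identical(regress_confounds(X, matrix(0, nt, 0)), X)
  # dependent columns dropped with a warning
  expect_warning(regress_confounds(X, cbind(C, C[, 1])), "dependent")
})

test_that("with no motion and no confounds the pipeline is smooth + filter", {
  q <- quiet_pd_sim(n_frames = 800, rng_seed = 13)
  s <- q$sim; atlas <- q$atlas
  st <- denoise_strategy(scrub_metric = "none", confound_method = "none",
                         freq_filter = "highpass")
  res <- denoise_pipeline(s$pd, s$vel, st, atlas$masks)
  manual <- frequency_filter(gaussian_smooth(s$pd, 0.3), "highpass")
  expect_equal(res$clean$data, manual$data, tolerance = 1e-12)
  expect_equal(res$tdof_pct, 100)
})

test_that("the canonical stage order matters on surge-bearing data", {
  # applying the frequency filter before scrub-replacement lets surges ring
  # through the filter; the pipeline's replace-then-filter order must differ
  cfg <- sim_config(grid_shape = c(8, 8), n_blocks = 900, rng_seed = 23,
                    motion_events = list(list(block = 450,
                                              velocity_mm_s = 0.05,
                                              surge = 4)))
  s <- simulate_power_doppler(cfg)
  masks <- list(brain = full_mask(c(8, 8)))
  st <- denoise_strategy(scrub_metric = "gv", confound_method = "none",
                         freq_filter = "bandpass")
  res <- denoise_pipeline(s$pd, s$vel, st, masks)
  qc <- temporal_qc(s$pd, s$vel, masks$brain)
  mask <- detect_high_motion(qc, st, s$pd$fs_Hz)
  swapped <- scrub_replace(frequency_filter(gaussian_smooth(s$pd, 0.3),
                                            "bandpass"), mask)
  swapped <- drop_scrubbed(swapped, mask)$data
  expect_gt(max(abs(swapped$data - res$clean$data)), 1e-6)
})

test_that("scrubbing flags exactly the injected motion frames end to end", {
  cfg <- sim_config(grid_shape = c(12, 12), n_blocks = 1000, rng_seed = 29,
                    motion_events = lapply(c(100, 400, 401, 800),
                                           function(b) list(block = b,
                                                            velocity_mm_s = 0.05,
                                                            surge = 3)))
  s <- simulate_power_doppler(cfg)
  masks <- list(brain = full_mask(c(12, 12)))
  qc <- temporal_qc(s$pd, s$vel, masks$brain)
  truth <- which(s$truth$motion_mask)
  st_gv <- denoise_strategy(scrub_metric = "gv", confound_method = "none")
  expect_identical(which(detect_high_motion(qc, st_gv, 2.5)$flagged), truth)
  # rDVARS reacts to signal *transitions* (backward differences): it flags
  # the entry into and the exit out of every surge period, so every flag
  # lies in the events or their immediate successors, every isolated event
  # is flagged, and so is the first frame of every consecutive run
  st_rd <- denoise_strategy(scrub_metric = "rdvars", confound_method = "none")
  fl <- which(detect_high_motion(qc, st_rd, 2.5)$flagged)
  expect_true(all(fl %in% sort(union(truth, truth + 1L))))
  run_starts <- truth[c(TRUE, diff(truth) > 1)]
  expect_true(all(run_starts %in% fl))
  expect_true(all((truth[c(diff(truth) > 1, TRUE)] + 1L) %in% fl))
})
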