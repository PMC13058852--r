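test_that("sphere membership uses the voxel-center inclusion rule", {
  # radius 0.3 mm on a 0.1 mm grid: 123 voxels in 3D, 29 in 2D
  s <- seed_spec("c", c(1, 1, 1), 0.3)
  idx <- fusiclean:::seed_voxels(s, c(21, 21, 21), 0.1)
  expect_length(idx, 123)
  s2 <- seed_spec("c2", c(1, 1), 0.3)
  expect_length(fusiclean:::seed_voxels(s2, c(21, 21), 0.1), 29)
  expect_error(fusiclean:::seed_voxels(seed_spec("far", c(99, 99), 0.3),
                                       c(5, 5), 0.1), "no voxel")
})

test_that("seed signal averages the sphere and reduces to one voxel", {
  grid <- c(9, 9)
  set.seed(41)
  m <- matrix(rnorm(20 * 81), 20, 81)
  pd <- pd_from_matrix(m, grid)
  tiny <- seed_spec("one", c(0.4, 0.4), 0.049)
  expect_equal(seed_signal(pd, tiny), m[, 5 + 4 * 9])
  # uniform volume: seed signal equals the global signal
  u <- pd_from_matrix(matrix(rep(1:20, 81), 20, 81), grid)
  expect_equal(seed_signal(u, seed_spec("s", c(0.4, 0.4), 0.3)),
               as.numeric(1:20))
})

test_that("seed maps are Pearson correlations with affine invariance", {
  grid <- c(5, 5)
  set.seed(42)
  sig <- rnorm(200)
  m <- matrix(rnorm(200 * 25), 200, 25)
  m[, 13] <- sig          # the seed voxel itself
  m[, 1] <- sig            # identical copy -> r = 1
  m[, 2] <- -sig           # sign flip -> r = -1
  pd <- pd_from_matrix(m, grid)
  seed <- seed_spec("v13", c(0.2, 0.2), 0.049)
  mp <- seed_map(pd, seed, full_mask(grid))
  expect_equal(mp$r[1, 1], 1, tolerance = 1e-12)
  expect_equal(mp$r[2, 1], -1, tolerance = 1e-12)
  expect_lt(max(abs(mp$r[cbind(c(3, 4), c(2, 3))])), 0.2)
  # affine rescaling of voxels leaves r unchanged
  m2 <- sweep(sweep(m, 2, runif(25, 0.5, 2), `*`), 2, rnorm(25), `+`)
  mp2 <- seed_map(pd_from_matrix(m2, grid), seed, full_mask(grid))
  expect_equal(mp2$r, mp$r, tolerance = 1e-10)
  # zero-variance voxels get r = 0 and are flagged
  m3 <- m; m3[, 25] <- 7
  mp3 <- seed_map(pd_from_matrix(m3, grid), seed, full_mask(grid))
  expect_equal(mp3$r[5, 5], 0)
  expect_identical(mp3$zero_variance, 25L)
  expect_error(seed_map(pd_from_matrix(matrix(1, 50, 25), grid), seed,
                        full_mask(grid)), "constant seed")
})

test_that("independent voxels stay near zero correlation at n = 1000", {
  grid <- c(2, 2)
  set.seed(43)
  m <- cbind(rnorm(1000), matrix(rnorm(3000), 1000, 3))
  pd <- pd_from_matrix(m, grid)
  mp <- seed_map(pd, seed_spec("s", c(0, 0), 0.049), full_mask(grid))
  expect_lt(max(abs(mp$r[-1])), 0.1)
})

test_that("Fisher averaging obeys its closed-form identities", {
  grid <- c(2, 2)
  mk <- function(r) structure(list(r = array(r, grid),
                                   seed = seed_spec("s", c(0, 0)),
                                   n_frames = 10L), class = "seed_map")
  one <- mk(0.37)
  expect_equal(average_maps_fisher(list(one))$r, one$r)
  expect_equal(average_maps_fisher(list(mk(0.5), mk(-0.5)))$r,
               array(0, grid))
  want <- tanh((atanh(0.2) + atanh(0.6)) / 2)
  expect_equal(average_maps_fisher(list(mk(0.2), mk(0.6)))$r[1, 1], want)
  # r = 1 is clipped, not infinite
  expect_true(all(is.finite(average_maps_fisher(list(mk(1), mk(0)))$r)))
  expect_error(average_maps_fisher(list()), "at least one")
})

test_that("top-fraction thresholding counts voxels and breaks ties by index", {
  grid <- c(10, 10)
  r <- array(0.1, grid)
  r[1:10] <- 0.9
  mask <- full_mask(grid)
  th <- threshold_top_fraction(r, mask, 0.10)
  expect_equal(sum(th), 10)
  expect_true(all(which(th) == 1:10))
  expect_equal(sum(threshold_top_fraction(r, mask, 1)), 100)
  # ties: all equal values -> lowest linear indices win
  req <- array(0.5, grid)
  expect_identical(which(threshold_top_fraction(req, mask, 0.05)), 1:5)
  # signed mode ranks negatives low
  rs <- array(0, grid); rs[3] <- -0.99; rs[7] <- 0.2
  expect_identical(which(threshold_top_fraction(rs, mask, 0.01,
                                                by_absolute = FALSE)), 7L)
  expect_identical(which(threshold_top_fraction(rs, mask, 0.01,
                                                by_absolute = TRUE)), 3L)
})

test_that("seed maps recover the planted bilateral networks", {
  # pure network + noise model (no brain-wide physiological component), so
  # the recovery of the planted structure is tested in isolation
  atlas <- synthetic_atlas(c(16, 16))
  cfg <- sim_config(grid_shape = c(16, 16), n_blocks = 1000, rng_seed = 47,
                    network_rois = atlas$network_rois, global_amp = 0)
  s <- simulate_power_doppler(cfg)
  st <- denoise_strategy(scrub_metric = "none", confound_method = "none")
  res <- denoise_pipeline(s$pd, s$vel, st, atlas$masks)
  mp <- seed_map(res$clean, atlas$seeds[[1]], atlas$masks$brain)
  top <- threshold_top_fraction(mp, atlas$masks$brain, 0.10)
  netvox <- which(s$truth$network_membership == 1)
  expect_gte(sum(top[netvox]) / length(netvox), 0.8)
})
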