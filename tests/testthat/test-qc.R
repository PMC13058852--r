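test_that("spatial QC maps follow their definitions", {
  grid <- c(2, 2)
  pd <- pd_from_matrix(matrix(c(1, 3), nrow = 2, ncol = 4), grid)
  vel <- pd_from_matrix(matrix(0.02, 2, 4), grid, kind = "velocity")
  sq <- spatial_qc(pd, vel)
  expect_equal(sq$mean_pd, array(2, grid))
  expect_equal(sq$cv, array(0.5, grid))  # population sd 1 over mean 2
  expect_equal(sq$mean_velocity, array(0.02, grid))
  # constant series: zero CV
  pdc <- pd_from_matrix(matrix(5, 10, 4), grid)
  expect_equal(spatial_qc(pdc, vel = pd_from_matrix(matrix(0, 10, 4), grid,
                                                    kind = "velocity"))$cv,
               array(0, grid))
})

test_that("CV estimate matches the lognormal closed form", {
  set.seed(4)
  n <- 10000
  m <- matrix(exp(rnorm(n * 4, sd = 0.1)), n, 4)
  pd <- pd_from_matrix(m, c(2, 2))
  vel <- pd_from_matrix(matrix(0, n, 4), c(2, 2), kind = "velocity")
  want <- sqrt(exp(0.1^2) - 1)
  expect_equal(mean(spatial_qc(pd, vel)$cv), want, tolerance = 0.1)
})

test_that("rGS is the percent excursion over the first-decile baseline", {
  grid <- c(2, 2)
  mask <- full_mask(grid)
  pd <- pd_from_matrix(matrix(7, 50, 4), grid)
  expect_equal(rgs(pd, mask), rep(0, 50))
  # 100 frames at 10, one at 12: D1 = 10 (type-7 quantile), peak 20%
  gs <- c(rep(10, 99), 12)
  pd2 <- pd_from_matrix(matrix(gs, 100, 4), grid)
  expect_equal(max(rgs(pd2, mask)), 20)
  # invariance under positive rescaling
  pd3 <- pd_from_matrix(matrix(gs * 37, 100, 4), grid)
  expect_equal(rgs(pd3, mask), rgs(pd2, mask))
  expect_error(rgs(pd, array(FALSE, grid)), "empty")
})

test_that("GV averages absolute velocity over the mask and scales with it", {
  grid <- c(2, 2)
  mask <- full_mask(grid)
  v <- pd_from_matrix(matrix(0.02, 5, 4), grid, kind = "velocity")
  expect_equal(gv(v, mask), rep(0.02, 5))
  half <- pd_from_matrix(cbind(matrix(0, 5, 2), matrix(0.04, 5, 2)), grid,
                         kind = "velocity")
  expect_equal(gv(half, mask), rep(0.02, 5))
  expect_equal(gv(pd_from_matrix(matrix(0.06, 5, 4), grid,
                                 kind = "velocity"), mask),
               3 * gv(v, mask))
})

test_that("rDVARS has a unit null baseline under white and AR(1) noise", {
  set.seed(14)
  grid <- c(20, 25)  # 500 voxels
  n <- 2000
  for (rho in c(0, 0.5)) {
    e <- matrix(rnorm(n * 500), n, 500)
    if (rho > 0)
      for (t in 2:n) e[t, ] <- rho * e[t - 1, ] + sqrt(1 - rho^2) * e[t, ]
    pd <- pd_from_matrix(100 + e, grid)
    r <- rdvars(pd, full_mask(grid))
    expect_true(is.na(r[1]))
    expect_gt(median(r, na.rm = TRUE), 0.9)
    expect_lt(median(r, na.rm = TRUE), 1.1)
  }
})

test_that("rDVARS is scale invariant, and zero for constant data", {
  set.seed(3)
  grid <- c(4, 4)
  m <- matrix(rnorm(100 * 16, mean = 50), 100, 16)
  a <- rdvars(pd_from_matrix(m, grid), full_mask(grid))
  b <- rdvars(pd_from_matrix(m * 13, grid), full_mask(grid))
  expect_equal(a, b, tolerance = 1e-12)
  cst <- rdvars(pd_from_matrix(matrix(5, 10, 16), grid), full_mask(grid))
  expect_equal(cst[-1], rep(0, 9))
})

test_that("an intensity doubling spikes rDVARS at that frame and the next only", {
  set.seed(6)
  grid <- c(6, 6)
  m <- matrix(rnorm(300 * 36, mean = 100, sd = 1), 300, 36)
  m[150, ] <- m[150, ] * 2
  r <- rdvars(pd_from_matrix(m, grid), full_mask(grid))
  big <- which(r > 10)
  expect_identical(big, c(150L, 151L))
})

test_that("the temporal QC table is well-formed", {
  grid <- c(4, 4)
  set.seed(2)
  pd <- pd_from_matrix(matrix(rnorm(50 * 16, 100), 50, 16), grid)
  vel <- pd_from_matrix(matrix(abs(rnorm(50 * 16, 0.02, 1e-3)), 50, 16),
                        grid, kind = "velocity")
  qc <- temporal_qc(pd, vel, full_mask(grid))
  expect_named(qc, c("frame", "t_sec", "rgs_pct", "gv_mm_s", "rdvars"))
  expect_equal(qc$t_sec[2] - qc$t_sec[1], 1 / 2.5)
  expect_true(is.na(qc$rdvars[1]) && !anyNA(qc$rdvars[-1]))
})

test_that("extreme-intensity frame averages isolate surge periods", {
  grid <- c(4, 4)
  m <- matrix(100, 100, 16)
  m[40, ] <- 400
  pd <- pd_from_matrix(m, grid)
  ex <- intensity_extreme_means(pd, brain_mask = full_mask(grid),
                                fraction = 0.01)
  expect_equal(ex$pd_high, array(400, grid))
  expect_equal(ex$pd_low, array(100, grid))
  expect_equal(ex$pd_rel_diff, array(3, grid))
})
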