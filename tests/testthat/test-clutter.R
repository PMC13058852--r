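test_that("Gram eigendecomposition matches its definition and an SVD oracle", {
  # diagonal case: eigenvalues are the squared row norms, descending
  M <- matrix(c(1, 0, 0, 2), 2, 2)
  e <- gram_eigendecomposition(M)
  expect_equal(e$energies, c(4, 1))

  set.seed(21)
  M <- matrix(complex(real = rnorm(500), imaginary = rnorm(500)), 10, 50)
  e <- gram_eigendecomposition(M)
  # trace identity
  expect_equal(sum(e$energies), sum(Mod(M)^2), tolerance = 1e-10)
  # squared singular values from an independent SVD
  sv <- svd(M)$d
  expect_equal(e$energies, sv^2, tolerance = 1e-8)
  # orthonormal vectors
  G <- Conj(t(e$vectors)) %*% e$vectors
  expect_lt(max(Mod(G - diag(nrow(G)))), 1e-8)
})

test_that("static selection takes the top-T components", {
  b <- list(energies = c(10, 5, 2, 1), total_energy = 18,
            vectors = diag(4))
  class(b) <- "eigen_basis"
  expect_identical(select_clutter_static(b, 0L), integer(0))
  expect_identical(select_clutter_static(b, 2L), 1:2)
  expect_error(select_clutter_static(b, 5L), "between 0 and")
})

test_that("constant-energy selection matches a brute-force search over k", {
  b <- list(energies = c(10, 5, 2, 1), total_energy = 18, vectors = diag(4))
  class(b) <- "eigen_basis"
  expect_length(select_clutter_constant_energy(b, 4), 2)  # residual 3; k=1 -> 8
  expect_length(select_clutter_constant_energy(b, 18), 0)
  expect_length(select_clutter_constant_energy(b, 0), 4)

  set.seed(5)
  for (rep in 1:20) {
    en <- sort(rexp(12), decreasing = TRUE)
    bb <- list(energies = en, total_energy = sum(en), vectors = diag(12))
    class(bb) <- "eigen_basis"
    C <- runif(1, 0, sum(en))
    k <- length(select_clutter_constant_energy(bb, C))
    # brute force: smallest k with residual <= C
    resid <- sum(en) - cumsum(c(0, en))
    k_oracle <- which(resid <= C)[1] - 1
    expect_equal(k, k_oracle)
    # residual is maximal among admissible choices
    expect_lte(resid[k + 1], C)
    if (k > 0) expect_gt(resid[k], C)
  }
})

test_that("the acquisition threshold C is the minimum static residual", {
  set.seed(9)
  mk <- function() {
    s <- array(complex(real = rnorm(400), imaginary = rnorm(400)),
               dim = c(25, 4, 4))
    iq_block(s, f_pulse_Hz = 15.625e6, f_iq_Hz = 500)
  }
  blocks <- list(mk(), mk(), mk())
  Tn <- 5L
  resid <- sapply(blocks, function(b) {
    e <- gram_eigendecomposition(fusiclean:::block_matrix(b))
    e$total_energy - sum(e$energies[1:Tn])
  })
  expect_equal(compute_energy_threshold(blocks, Tn), min(resid),
               tolerance = 1e-10)
  # single block: C equals its own residual
  expect_equal(compute_energy_threshold(blocks[1], Tn), resid[1],
               tolerance = 1e-10)
  # identical blocks: the adaptive filter removes exactly T vectors
  same <- list(blocks[[1]], blocks[[1]])
  C <- compute_energy_threshold(same, Tn)
  e <- gram_eigendecomposition(fusiclean:::block_matrix(same[[1]]))
  expect_length(select_clutter_constant_energy(e, C), Tn)
})

test_that("subspace regression conserves energy and is idempotent", {
  set.seed(17)
  X <- matrix(complex(real = rnorm(2000), imaginary = rnorm(2000)), 20, 100)
  e <- gram_eigendecomposition(X)
  U <- e$vectors[, 1:3, drop = FALSE]
  Xf <- apply_clutter_filter(X, U)
  # identity with empty set
  expect_identical(apply_clutter_filter(X, NULL), X)
  # energy conservation
  expect_equal(sum(Mod(Xf)^2) + sum(e$energies[1:3]), sum(Mod(X)^2),
               tolerance = 1e-6 * sum(Mod(X)^2))
  # residual orthogonal to the removed subspace
  expect_lt(max(Mod(Conj(t(U)) %*% Xf)), 1e-8 * sqrt(sum(Mod(X)^2)))
  # idempotence
  expect_equal(apply_clutter_filter(Xf, U), Xf, tolerance = 1e-10)
  # equivalence with the truncated-SVD residual
  sv <- svd(X)
  Xo <- X - sv$u[, 1:3] %*% diag(sv$d[1:3]) %*% Conj(t(sv$v[, 1:3]))
  expect_equal(Xf, Xo, tolerance = 1e-8)
  # rank-1 block fully removed by its own singular vector
  X1 <- outer(complex(real = rnorm(20), imaginary = rnorm(20)),
              complex(real = rnorm(30), imaginary = rnorm(30)))
  e1 <- gram_eigendecomposition(X1)
  expect_lt(sqrt(sum(Mod(apply_clutter_filter(X1, e1$vectors[, 1,
                                                             drop = FALSE]))^2)),
            1e-8 * sqrt(sum(Mod(X1)^2)))
})

test_that("power Doppler integration averages the squared modulus", {
  X <- matrix(exp(1i * runif(30)), 10, 3)
  expect_equal(power_doppler_integrate(X), rep(1, 3))
  expect_equal(power_doppler_integrate(matrix(0i, 4, 2)), c(0, 0))
  X2 <- matrix(c(1, 3) + 0i, 2, 1)
  expect_equal(power_doppler_integrate(X2), 5)
})

test_that("clutter filtering recovers the blood CBV time course on phantoms", {
  cfg <- sim_config(grid_shape = c(12, 12), n_blocks = 40, rng_seed = 7,
                    network_rois = bilateral_rois(c(12, 12)))
  sim <- simulate_iq(cfg)
  # the static filter (T at least the clutter rank) preserves the slow CBV
  # signal; the constant-energy filter clamps residual energy per block and
  # may clip part of it (the same mechanism that flattens the global signal)
  res <- iq_to_power_doppler(sim$blocks, clutter_filter_spec("static", 6L))
  pdm <- fusiclean:::series_matrix(res$pd)
  net <- which(sim$truth$network_membership == 1)
  cc <- cor(rowMeans(pdm[, net]), sim$truth$true_cbv[, net[1]])
  expect_gt(cc, 0.9)
  # constant-energy residuals never exceed C
  spec <- clutter_filter_spec("constant_energy", 6L)
  res <- iq_to_power_doppler(sim$blocks, spec)
  for (b in sim$blocks[1:5]) {
    e <- gram_eigendecomposition(fusiclean:::block_matrix(b))
    k <- length(select_clutter_constant_energy(e, res$energy_threshold))
    expect_lte(e$total_energy - sum(e$energies[seq_len(k)]),
               res$energy_threshold * (1 + 1e-10))
  }
})

test_that("temporal high-pass removes DC and keeps fast blood tones", {
  X <- matrix(1 + 0i, 200, 4)
  Xf <- temporal_highpass_iq(X, 500)
  expect_lt(sum(Mod(Xf)^2), 1e-6 * sum(Mod(X)^2))
  expect_error(temporal_highpass_iq(X, 30), "Nyquist")
})
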