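#' Configuration for synthetic fUSI acquisitions
#'
#' Describes a synthetic awake-brain acquisition with known ground truth.
#' The signal model encodes the premise of eigen-subspace clutter filtering:
#' tissue clutter is high-energy and spatiotemporally correlated (a low-rank
#' component orders of magnitude stronger than blood), blood scatterers are
#' low-energy with per-voxel Doppler shifts and slow bilateral cerebral blood
#' volume (CBV) fluctuations, and transient motion events add an axial phase
#' ramp plus an energy surge to the clutter.
#'
#' @param grid_shape Integer vector of voxels per spatial axis (2 or 3 axes).
#' @param voxel_size_mm Isotropic voxel spacing in mm.
#' @param f_pulse_Hz Transmitted pulse frequency (Hz).
#' @param c_m_per_s Speed of sound (m/s).
#' @param f_iq_Hz Compound frame rate after beamforming (Hz).
#' @param block_len Compound frames per block (one power Doppler volume per
#'   block).
#' @param n_blocks Acquisition length in blocks.
#' @param clutter_energy Clutter-to-blood total energy ratio (dimensionless,
#'   much greater than 1). Not quantified in vivo; the default 100 is a
#'   modeling choice that keeps the clutter and blood subspaces separable.
#' @param motion_events List of events, each a list with elements `block`
#'   (1-based block index), `velocity_mm_s` (axial tissue velocity during the
#'   event) and `surge` (multiplicative energy factor, e.g. 3 for a +200\%
#'   surge).
#' @param network_rois List of networks; each network is a list of integer
#'   vectors of linear voxel indices that share one latent slow CBV signal
#'   (e.g. bilateral region pairs).
#' @param network_amp Fractional CBV amplitude of the latent network signals.
#' @param global_amp Fractional amplitude of a brain-wide slow physiological
#'   fluctuation shared by all voxels (vasomotion-like); this is what
#'   global-signal regression chiefly removes in real data.
#' @param noise_sd Fractional standard deviation of the temporal noise at the
#'   power Doppler level.
#' @param ar1_rho AR(1) coefficient of the power-Doppler-level temporal
#'   noise, in `[0, 1)`.
#' @param rng_seed Integer root seed; every component draws from its own
#'   substream derived from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(grid_shape = c(16, 16), voxel_size_mm = 0.1,
                       f_pulse_Hz = 15.625e6, c_m_per_s = 1540,
                       f_iq_Hz = 500, block_len = 200, n_blocks = 50,
                       clutter_energy = 100, motion_events = list(),
                       network_rois = list(), network_amp = 0.05,
                       global_amp = 0.02, noise_sd = 0.02, ar1_rho = 0.3,
                       rng_seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_mm = voxel_size_mm, f_pulse_Hz = f_pulse_Hz,
              c_m_per_s = c_m_per_s, f_iq_Hz = f_iq_Hz,
              block_len = as.integer(block_len),
              n_blocks = as.integer(n_blocks),
              clutter_energy = clutter_energy,
              motion_events = motion_events,
              network_rois = network_rois, network_amp = network_amp,
              global_amp = global_amp, noise_sd = noise_sd, ar1_rho = ar1_rho,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) stop("invalid sim_config field `", field, "`: ",
                                   why, call. = FALSE)
  if (length(cfg$grid_shape) < 2L || length(cfg$grid_shape) > 3L ||
      any(cfg$grid_shape < 1L)) bad("grid_shape", "need 2 or 3 positive sizes")
  if (cfg$block_len < 2L) bad("block_len", "must be at least 2")
  if (cfg$n_blocks < 1L) bad("n_blocks", "must be at least 1")
  if (cfg$clutter_energy <= 1) bad("clutter_energy", "must exceed 1")
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) bad("ar1_rho", "must be in [0, 1)")
  if (cfg$noise_sd < 0) bad("noise_sd", "must be nonnegative")
  if (!is.null(cfg$global_amp) && cfg$global_amp < 0)
    bad("global_amp", "must be nonnegative")
  for (ev in cfg$motion_events) {
    if (is.null(ev$block) || is.null(ev$velocity_mm_s) || is.null(ev$surge))
      bad("motion_events", "each event needs block, velocity_mm_s, surge")
    if (ev$block < 1 || ev$block > cfg$n_blocks)
      bad("motion_events", paste0("event block ", ev$block,
                                  " outside 1..n_blocks"))
    if (ev$surge <= 0) bad("motion_events", "surge must be positive")
  }
  nvox <- prod(cfg$grid_shape)
  for (net in cfg$network_rois) {
    if (!is.list(net)) bad("network_rois", "each network must be a list of
 voxel index vectors")
    for (roi in net)
      if (any(roi < 1) || any(roi > nvox))
        bad("network_rois", "voxel index outside the grid")
  }
  cfg
}

# substream seeding: one root seed, a fixed offset per model component, so
# that adding a component does not perturb the draws of the others
with_substream <- function(cfg, offset, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((cfg$rng_seed %% 100000L) * 19997L + offset)
  force(expr)
}

# smooth random spatial field on the grid (unit variance-ish)
smooth_field <- function(grid, sigma_vox = 2) {
  x <- array(stats::rnorm(prod(grid)), dim = grid)
  x <- gaussian_smooth_array(x, sigma_vox)
  x / stats::sd(x)
}

# slow latent signal: white noise low-passed to the hemodynamic band
slow_signal <- function(n, fs, f_hi = 0.08) {
  x <- stats::rnorm(n + 200)
  f <- butter_sos(2, min(f_hi, fs / 2 * 0.8), fs, "low")
  y <- sos_filter(x, f)
  y <- y[-seq_len(200)]
  as.numeric(scale(y))
}

event_table <- function(cfg) {
  blocks <- vapply(cfg$motion_events, function(e) as.integer(e$block), 1L)
  vel <- vapply(cfg$motion_events, function(e) as.numeric(e$velocity_mm_s), 1)
  surge <- vapply(cfg$motion_events, function(e) as.numeric(e$surge), 1)
  list(blocks = blocks, vel = vel, surge = surge)
}

#' Simulate beamformed I/Q blocks with known ground truth
#'
#' Generates `n_blocks` compound I/Q blocks. The clutter component is a
#' low-rank (rank 4) sum of smooth complex spatial patterns times smooth
#' temporal envelopes, scaled so that its total energy is `clutter_energy`
#' times the blood energy. During a motion event the clutter acquires a
#' per-frame axial phase ramp `exp(1i * 4 * pi * f_pulse * v * t / (c * f_iq))`
#' and its amplitude is multiplied by `sqrt(surge)`. The blood component has
#' per-voxel random scatterer phase, a Doppler shift drawn uniformly from
#' +/-[2, 10] mm/s (above the ~1 mm/s clutter cutoff so high-pass filtering
#' retains it), and amplitude modulated by the slow true CBV signal. Complex
#' white noise is added on top.
#'
#' @param config A [sim_config()].
#' @return A list with `blocks` (list of [iq_block()]) and `truth`, a list
#'   holding `true_cbv` (block-rate matrix, block x voxel), the per-block
#'   `true_axial_velocity` (mm/s), the logical `motion_mask` per block, and
#'   `network_membership` (integer per voxel, 0 = background).
#' @export
simulate_iq <- function(config) {
  cfg <- validate_sim_config(config)
  grid <- cfg$grid_shape
  nvox <- prod(grid)
  L <- cfg$block_len
  nb <- cfg$n_blocks
  nt <- L * nb
  ev <- event_table(cfg)

  # --- blood component -------------------------------------------------
  blood <- with_substream(cfg, 11L, {
    v_mag <- stats::runif(nvox, 2, 10) * sample(c(-1, 1), nvox, replace = TRUE)
    f_d <- 2 * cfg$f_pulse_Hz * (v_mag / 1000) / cfg$c_m_per_s  # Hz
    phi0 <- stats::runif(nvox, 0, 2 * pi)
    amp0 <- 0.8 + 0.4 * stats::runif(nvox)
    list(f_d = f_d, phi0 = phi0, amp0 = amp0)
  })

  # slow CBV modulation at block rate (networks + per-voxel jitter)
  fs_pd <- cfg$f_iq_Hz / L
  cbv <- with_substream(cfg, 12L, {
    m <- matrix(0, nrow = nb, ncol = nvox)
    membership <- integer(nvox)
    for (k in seq_along(cfg$network_rois)) {
      lat <- slow_signal(nb, fs_pd)
      for (roi in cfg$network_rois[[k]]) {
        m[, roi] <- m[, roi] + cfg$network_amp * lat
        membership[roi] <- k
      }
    }
    list(m = m, membership = membership)
  })

  # --- clutter component ----------------------------------------------
  rank_c <- 4L
  clut <- with_substream(cfg, 13L, {
    spat <- lapply(seq_len(rank_c), function(j)
      complex(real = as.vector(smooth_field(grid, 2)),
              imaginary = 0.3 * as.vector(smooth_field(grid, 2))))
    env <- lapply(seq_len(rank_c), function(j) {
      e <- slow_signal(nt, cfg$f_iq_Hz, f_hi = 2)
      1 + 0.15 * e
    })
    list(spat = spat, env = env)
  })

  noise_draw <- with_substream(cfg, 14L, {
    complex(real = stats::rnorm(nt * nvox), imaginary = stats::rnorm(nt * nvox))
  })
  dim(noise_draw) <- c(nt, nvox)

  dphi_per_v <- 4 * pi * cfg$f_pulse_Hz / (cfg$c_m_per_s * cfg$f_iq_Hz * 1000)

  blocks <- vector("list", nb)
  true_v <- numeric(nb)
  motion_mask <- logical(nb)

  # energies for scaling: compute blood first, then scale clutter patterns
  tloc <- seq_len(L) - 1
  blood_energy <- 0
  blood_blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    tg <- (b - 1) * L + tloc
    # frames x voxels: amp * sqrt(1 + cbv) * exp(i(2 pi f_d t / f_iq + phi0))
    phase <- outer(tg, blood$f_d) * (2 * pi / cfg$f_iq_Hz)
    phase <- sweep(phase, 2, blood$phi0, `+`)
    amp <- blood$amp0 * sqrt(pmax(1 + cbv$m[b, ], 0.05))
    m <- sweep(exp(1i * phase), 2, amp, `*`)
    blood_blocks[[b]] <- m
    blood_energy <- blood_energy + sum(Mod(m)^2)
  }

  clut_energy_raw <- 0
  clut_blocks <- vector("list", nb)
  for (b in seq_len(nb)) {
    tg <- (b - 1) * L + tloc
    m <- matrix(0 + 0i, nrow = L, ncol = nvox)
    for (j in seq_len(rank_c))
      m <- m + outer(clut$env[[j]][tg + 1], clut$spat[[j]])
    iev <- match(b, ev$blocks)
    if (!is.na(iev)) {
      ramp <- exp(1i * dphi_per_v * ev$vel[iev] * tloc)
      m <- m * ramp * sqrt(ev$surge[iev])
      true_v[b] <- ev$vel[iev]
      motion_mask[b] <- TRUE
    }
    clut_blocks[[b]] <- m
    clut_energy_raw <- clut_energy_raw + sum(Mod(m)^2)
  }
  scale_c <- sqrt(cfg$clutter_energy * blood_energy / clut_energy_raw)

  noise_scale <- sqrt(0.01 * blood_energy / (2 * nt * nvox))
  for (b in seq_len(nb)) {
    rows <- (b - 1) * L + seq_len(L)
    s <- scale_c * clut_blocks[[b]] + blood_blocks[[b]] +
      noise_scale * noise_draw[rows, , drop = FALSE]
    dim(s) <- c(L, grid)
    blocks[[b]] <- iq_block(s, f_pulse_Hz = cfg$f_pulse_Hz,
                            c_m_per_s = cfg$c_m_per_s, f_iq_Hz = cfg$f_iq_Hz,
                            voxel_size_mm = cfg$voxel_size_mm)
  }

  truth <- list(true_cbv = cbv$m, true_axial_velocity = true_v,
                motion_mask = motion_mask,
                network_membership = cbv$membership)
  list(blocks = blocks, truth = truth, config = cfg)
}

#' Simulate a power-Doppler-level acquisition with known ground truth
#'
#' Generates a power Doppler series directly at the Doppler frame rate:
#' a smooth positive baseline map times
#' `(1 + network signals + AR(1) noise)`, with multiplicative intensity
#' surges at the configured motion events (a surge factor of 3 is a +200\%
#' excursion, the order of magnitude seen during awake-animal movements).
#' A matching absolute axial-velocity series is generated alongside: a quiet
#' baseline of 0.02 mm/s with small jitter, elevated to the event velocity
#' during motion events, so velocity-based quality-control metrics can be
#' exercised without I/Q-level simulation.
#'
#' @param config A [sim_config()]; one frame is produced per block.
#' @return A list with `pd` and `vel` ([fusi_series()] objects at the Doppler
#'   rate) and `truth` as in [simulate_iq()].
#' @export
simulate_power_doppler <- function(config) {
  cfg <- validate_sim_config(config)
  grid <- cfg$grid_shape
  nvox <- prod(grid)
  nb <- cfg$n_blocks
  fs <- cfg$f_iq_Hz / cfg$block_len
  ev <- event_table(cfg)

  baseline <- with_substream(cfg, 21L, {
    exp(0.5 * as.vector(smooth_field(grid, 3))) * 100
  })

  net <- with_substream(cfg, 22L, {
    m <- matrix(0, nrow = nb, ncol = nvox)
    membership <- integer(nvox)
    for (k in seq_along(cfg$network_rois)) {
      lat <- slow_signal(nb, fs)
      for (roi in cfg$network_rois[[k]]) {
        m[, roi] <- m[, roi] + cfg$network_amp * lat
        membership[roi] <- k
      }
    }
    list(m = m, membership = membership)
  })

  noise <- with_substream(cfg, 23L, {
    e <- matrix(stats::rnorm(nb * nvox), nrow = nb)
    if (cfg$ar1_rho > 0) {
      for (t in 2:nb) e[t, ] <- cfg$ar1_rho * e[t - 1, ] +
          sqrt(1 - cfg$ar1_rho^2) * e[t, ]
    }
    e * cfg$noise_sd
  })

  # brain-wide slow physiological fluctuation with smooth spatial loading
  glob <- with_substream(cfg, 25L, {
    ga <- if (is.null(cfg$global_amp)) 0 else cfg$global_amp
    if (ga > 0) {
      lat <- slow_signal(nb, fs)
      loading <- 1 + 0.3 * as.vector(smooth_field(grid, 3))
      ga * outer(lat, loading)
    } else matrix(0, nb, nvox)
  })

  x <- 1 + net$m + glob + noise
  x <- sweep(x, 2, baseline, `*`)

  true_v <- rep(0.02, nb)
  motion_mask <- logical(nb)
  if (length(ev$blocks)) {
    for (i in seq_along(ev$blocks)) {
      b <- ev$blocks[i]
      x[b, ] <- x[b, ] * ev$surge[i]
      true_v[b] <- ev$vel[i]
      motion_mask[b] <- TRUE
    }
  }

  vel_jitter <- with_substream(cfg, 24L, {
    abs(matrix(stats::rnorm(nb * nvox, sd = 1e-3), nrow = nb))
  })
  v <- sweep(vel_jitter, 1, true_v, `+`)

  pd <- fusi_series(array(pmax(x, 0), dim = c(nb, grid)), fs_Hz = fs,
                    voxel_size_mm = cfg$voxel_size_mm, kind = "pd")
  vel <- fusi_series(array(v, dim = c(nb, grid)), fs_Hz = fs,
                     voxel_size_mm = cfg$voxel_size_mm, kind = "velocity")
  truth <- list(true_cbv = net$m, true_axial_velocity = true_v,
                motion_mask = motion_mask,
                network_membership = net$membership)
  list(pd = pd, vel = vel, truth = truth, config = cfg)
}

#' Bilateral network regions on a rectangular grid
#'
#' Convenience builder for synthetic functional networks: pairs of square
#' regions mirrored across the grid's vertical midline, each pair sharing one
#' latent slow CBV signal. Used to give the synthetic power Doppler data a
#' known seed-based connectivity structure.
#'
#' @param grid_shape Two spatial sizes (z, x).
#' @param centers_z Row centers of the regions.
#' @param half_width Half-width of each square region in voxels.
#' @return A list suitable for `sim_config(network_rois = ...)`; each element
#'   is a list of two linear-index vectors (left and right region).
#' @export
bilateral_rois <- function(grid_shape, centers_z = NULL, half_width = 1L) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  if (is.null(centers_z)) centers_z <- round(c(0.3, 0.7) * nz)
  cl <- round(0.25 * nx); cr <- nx + 1 - cl
  lapply(centers_z, function(cz) {
    zi <- pmax(1, cz - half_width):pmin(nz, cz + half_width)
    roi <- function(cx) {
      xi <- pmax(1, cx - half_width):pmin(nx, cx + half_width)
      as.integer(outer(zi, (xi - 1) * nz, `+`))
    }
    list(left = roi(cl), right = roi(cr))
  })
}

#' Synthetic atlas: masks, networks and seeds for benchmark fixtures
#'
#' Builds a self-consistent "atlas" for a synthetic acquisition: a brain
#' mask (whole grid), a white-matter/CSF-like mask (two thin horizontal
#' bands away from the networks, roughly the 10-16\% of brain volume such
#' masks occupy in practice), three bilateral networks, and one seed per
#' network region (6 seeds), each centered on its region.
#'
#' @param grid_shape Two spatial sizes (z, x).
#' @param voxel_size_mm Voxel spacing (mm).
#' @return List with `masks` (list `brain`, `wm_csf`), `network_rois`
#'   (for [sim_config()]), and `seeds` (list of [seed_spec()]).
#' @export
synthetic_atlas <- function(grid_shape = c(16, 16), voxel_size_mm = 0.1) {
  nz <- grid_shape[1]; nx <- grid_shape[2]
  centers_z <- round(c(0.25, 0.5, 0.75) * nz)
  nets <- bilateral_rois(grid_shape, centers_z = centers_z, half_width = 1L)
  brain <- array(TRUE, dim = grid_shape)
  wm_csf <- array(FALSE, dim = grid_shape)
  band <- setdiff(seq_len(nz), unlist(lapply(centers_z, function(c) (c - 2):(c + 2))))
  wm_csf[band[c(1, length(band))], ] <- TRUE
  cl <- round(0.25 * nx); cr <- nx + 1 - cl
  names(nets) <- c("net1", "net2", "net3")
  seeds <- list()
  for (k in seq_along(nets)) {
    for (side in c("left", "right")) {
      cx <- if (side == "left") cl else cr
      seeds[[paste0("net", k, "_", side)]] <-
        seed_spec(paste0("net", k, "_", side),
                  center_mm = c((centers_z[k] - 1) * voxel_size_mm,
                                (cx - 1) * voxel_size_mm))
    }
  }
  list(masks = list(brain = brain, wm_csf = wm_csf),
       network_rois = nets, seeds = unname(seeds))
}


#' Synthetic benchmark dataset
#'
#' Builds the desk-scale benchmark cohort: `n_subjects` power-Doppler-level
#' acquisitions on the [synthetic_atlas()] grid, each with three bilateral
#' networks, a shared global physiological fluctuation, AR(1) noise, and
#' `n_events` motion events at random times with surge factors drawn
#' log-uniformly between 1.05 and 5 (so that some artifacts fall below the
#' 10\% rGS scrubbing threshold while velocity- and rDVARS-based detection
#' still see them) and an event tissue velocity of 0.05 mm/s over a
#' 0.02 mm/s quiet baseline.
#'
#' @param n_subjects Number of simulated animals.
#' @param n_frames Power Doppler frames per acquisition.
#' @param rng_seed Root seed for the whole cohort.
#' @param n_events Motion events per acquisition.
#' @param grid_shape Spatial grid.
#' @return A list with `dataset` (list of acquisitions: `pd`, `vel`,
#'   `subject`, `truth`), `atlas` (see [synthetic_atlas()]).
#' @export
synthetic_benchmark_dataset <- function(n_subjects = 8, n_frames = 1000,
                                        rng_seed = 1L, n_events = 12,
                                        grid_shape = c(16, 16)) {
  atlas <- synthetic_atlas(grid_shape)
  dataset <- lapply(seq_len(n_subjects), function(i) {
    seed_i <- (rng_seed %% 100000L) * 211L + i
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed_i)
    lo <- max(2L, round(0.03 * n_frames))
    hi <- n_frames - lo
    evb <- sort(sample(lo:hi, n_events))
    surges <- exp(stats::runif(n_events, log(1.05), log(5)))
    evs <- lapply(seq_len(n_events), function(j)
      list(block = evb[j], velocity_mm_s = 0.05, surge = surges[j]))
    cfg <- sim_config(grid_shape = grid_shape, n_blocks = n_frames,
                      rng_seed = seed_i + 7L,
                      network_rois = atlas$network_rois,
                      motion_events = evs)
    s <- simulate_power_doppler(cfg)
    list(pd = s$pd, vel = s$vel, subject = paste0("m", i), truth = s$truth)
  })
  list(dataset = dataset, atlas = atlas)
}
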