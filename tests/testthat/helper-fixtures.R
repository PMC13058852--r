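# shared fixture builders; everything is generated in code at test time

# complex tone block: IQ(t) = exp(i 2 pi f_d t / f_iq) at every voxel
tone_block <- function(f_d = 100, L = 200, grid = c(4, 4),
                       f_pulse_Hz = 15.625e6, c_m_per_s = 1540,
                       f_iq_Hz = 500) {
  t <- 0:(L - 1)
  s <- array(rep(exp(1i * 2 * pi * f_d * t / f_iq_Hz), prod(grid)),
             dim = c(L, grid))
  iq_block(s, f_pulse_Hz = f_pulse_Hz, c_m_per_s = c_m_per_s,
           f_iq_Hz = f_iq_Hz)
}

# pd series from a (time x voxels) matrix on a given grid
pd_from_matrix <- function(m, grid, fs_Hz = 2.5, voxel_size_mm = 0.1,
                           kind = "pd") {
  fusi_series(array(m, dim = c(nrow(m), grid)), fs_Hz = fs_Hz,
              voxel_size_mm = voxel_size_mm, kind = kind)
}

full_mask <- function(grid) array(TRUE, dim = grid)

# small motionless pd/vel pair with networks, for fc and denoise tests
quiet_pd_sim <- function(n_frames = 600, rng_seed = 42) {
  atlas <- synthetic_atlas(c(16, 16))
  cfg <- sim_config(grid_shape = c(16, 16), n_blocks = n_frames,
                    rng_seed = rng_seed, network_rois = atlas$network_rois)
  s <- simulate_power_doppler(cfg)
  list(sim = s, atlas = atlas)
}
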