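# shared fixtures: small, fast variants of the recording protocol and study

# full-length sweep at a reduced sampling rate; enough resolution for the
# slow (decay/off) phases and the I-V analysis
quick_protocol <- function(noise_sd = 0, sample_rate_Hz = 2000,
                           holding_mV = seq(-120, 60, by = 20)) {
  protocol_spec(holding_mV = holding_mV, light_on = 0.1, light_off = 0.6,
                sweep_s = 1.0, sample_rate_Hz = sample_rate_Hz,
                noise_sd = noise_sd)
}

# high-rate protocol for kinetic fits (resolves tau_on ~ 4.6 ms)
kinetic_protocol <- function(noise_sd = 0) {
  protocol_spec(light_on = 0.1, light_off = 0.6, sweep_s = 1.0,
                sample_rate_Hz = 10000, noise_sd = noise_sd)
}

# WT-like noiseless photocycle sweep scaled to a given stationary current
wt_like_trace <- function(I_ss_uA = -1, protocol = kinetic_protocol(),
                          params = photocycle_params()) {
  traj <- simulate_photocycle(params, protocol)
  ss <- chr2pore:::photocycle_steady_state(params)
  env <- (traj$O1 + params$gamma * traj$O2) / (ss[2] + params$gamma * ss[3])
  tevc_trace(traj$time, env * I_ss_uA, holding_mV = -120,
             light_on = protocol$light_on, light_off = protocol$light_off)
}

# tiny on-disk study for io/pipeline tests
small_study <- function(dir, constructs = c(WT = 3.11),
                        ions = c("Li", "Na", "K"),
                        noise_sd = 0, n_cells = 1, seed = 42,
                        sample_rate_Hz = 1000) {
  cfg <- study_config(
    constructs = constructs, ions = ions, n_cells = n_cells,
    protocol = quick_protocol(noise_sd = noise_sd,
                              sample_rate_Hz = sample_rate_Hz),
    expression_cv = if (noise_sd > 0) 0.2 else 0)
  generate_study(cfg, seed = seed, out_dir = dir)
  file.path(dir, "manifest.json")
}
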