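# shared fixtures, built once per test run

fx_protocol <- scan_protocol()
fx_tl_small <- events_to_timeline(build_sequence(range_spec("small"), fx_protocol, seed = 1))
fx_tl_large <- events_to_timeline(build_sequence(range_spec("large"), fx_protocol, seed = 2))
fx_tl_ctrl  <- events_to_timeline(build_sequence(range_spec("large_control"), fx_protocol, seed = 3))
fx_timelines <- list(small = fx_tl_small, large = fx_tl_large)

fx_grid <- fit_grid()
fx_U_small <- grid_predictions(fx_tl_small, fx_grid)
fx_U_large <- grid_predictions(fx_tl_large, fx_grid)

# width law used throughout the synthetic maps: linear FWHM = 6 + 2 * preferred
fx_width_law <- c(6, 2)

fx_sigma_for <- function(preferred) {
  sigma_from_fwhm_linear(preferred, fx_width_law[1] + fx_width_law[2] * preferred)
}

# simulate one voxel under the large design and fit the 8-run mean
fx_fit_sim_voxel <- function(preferred, sigma, sd = 0.5, n_runs = 8,
                             tl = fx_tl_large, U = fx_U_large) {
  y <- simulate_voxel(tuning_params(preferred, sigma), tl,
                      noise = noise_model(sd = sd), n_runs = n_runs)
  grid_fit(colMeans(y), tl, fx_grid, predictions = U)
}
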