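# Scenario presets and wrappers shared by simulation-based tests.

# strong-instrument estimation scenario: J valid instruments, mean
# per-SNP F well above 30, no pleiotropy unless overridden
est_scenario <- function(J = 100, seed = 1, theta = 0.2, ...) {
  scenario_config(
    J = J, tau2 = 8e-4, n_exposure = 3e5,
    n_cases = 58221, n_controls = 67694,
    theta_direct = theta, seed = seed, ...
  )
}

# simulate and return the kept harmonized exposure-outcome pairs
sim_hset <- function(cfg) {
  sim <- simulate_summary_stats(cfg)
  kept_pairs(harmonize(sim$exposure, sim$outcome))
}
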