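# Small simulation worlds shared across the test files.

desk_config <- function(n_side = 50) lattice_config(n_side = n_side)

empty_world <- function(n_side = 50) {
  cfg <- desk_config(n_side)
  list(cfg = cfg, field = build_obstacle_field(cfg))
}

# Ensemble of free (no-obstacle) lattice trajectories.
free_lattice_msd <- function(n_tracers, measure_ms, n_side = 100,
                             exclusion = FALSE, seed = 1, n_ens = 1,
                             n_record = 40) {
  cfg <- desk_config(n_side)
  field <- build_obstacle_field(cfg)
  trajs <- lapply(seq_len(n_ens), function(e) {
    pop <- place_tracers(cfg, field, n_tracers = n_tracers,
                         exclusion = exclusion, seed = derive_seed(seed, e, 1))
    simulate_lattice(cfg, field, pop, sim_schedule(measure_ms,
                                                   n_record = n_record),
                     seed = derive_seed(seed, e, 2))
  })
  ensemble_msd(trajs)
}

# Hand-built trajectory object with prescribed displacement matrices (um).
fake_trajectory <- function(times_ms, x, y) {
  structure(list(times_ms = times_ms, x = x, y = y,
                 bound = rep(FALSE, ncol(x)), engine = "lattice",
                 params = list(a_dt = 0)),
            class = "cd_trajectory")
}

# Exact power-law MSD profile <r^2> = 4 D t^alpha on a log grid.
powerlaw_profile <- function(alpha, D = 2e-4, n = 60, t_min = 1, t_max = 2000) {
  t <- exp(seq(log(t_min), log(t_max), length.out = n))
  structure(data.frame(time_ms = t, msd_um2 = 4 * D * t^alpha),
            class = c("msd_profile", "data.frame"))
}
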