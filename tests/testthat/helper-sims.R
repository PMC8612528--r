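# Shared simulated fixtures, built once per test run.

.sim_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .sim_cache)) assign(key, builder(), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# a "battery" configuration scheduling all four maneuver classes at flat
# rates across the ramp, for classifier studies
battery_config <- function(seed, noise = 0.05) {
  sim_config("HB_PLUS", seed = as.integer(seed), pos_noise_sd_cm = noise,
    maneuver_rates = list(
      S_BEND = list(temp = c(1, 2, 15), rate = c(0, 0.25, 0.25)),
      C_BEND_SINGLE = list(temp = c(1, 2, 15), rate = c(0, 0.25, 0.25)),
      C_BEND_MULTI = list(temp = c(1, 2, 15), rate = c(0, 0.25, 0.25)),
      WITHDRAWAL = list(temp = c(1, 2, 15), rate = c(0, 0.25, 0.25))),
    triplet_rate = list(temp = c(0, 20), rate = c(0, 0)),
    coupling = FALSE)
}

battery_sim_clean <- function() cache_get("battery_clean", function() {
  simulate_experiment(battery_config(11, noise = 0), opercular = FALSE)
})

battery_sim_noisy <- function() cache_get("battery_noisy", function() {
  simulate_experiment(battery_config(12, noise = 0.05), opercular = FALSE)
})

hbp_sim_coupled <- function() cache_get("hbp_coupled", function() {
  simulate_experiment(sim_config("HB_PLUS", seed = 3L, op_noise_sd_mm = 0))
})

hbp_sim_decoupled <- function() cache_get("hbp_decoupled", function() {
  simulate_experiment(sim_config("HB_PLUS", seed = 4L, coupling = FALSE))
})

# a short fast-ramp run for io round-trip mechanics (not study conditions)
short_sim <- function() cache_get("short_sim", function() {
  simulate_experiment(sim_config("HB_MINUS", seed = 21L, ramp_rate = 30,
                                 baseline_min = 2, t_loe_fixed = 5.5,
                                 dropout_rate = 0.002))
})

# match each ground-truth event to the nearest detection by onset time
match_events <- function(truth, detected) {
  vapply(truth$t_onset, function(t0) which.min(abs(detected$t_onset - t0)),
         integer(1))
}

# minimal classified-event table for laterality tests
lr_events <- function(pct, direction, near_wall = FALSE, klass = "C_BEND_SINGLE") {
  data.frame(klass = klass, direction = direction, pct_tloe = pct,
             near_wall = near_wall)
}

# schedule-only cohort run: five specimens' ground-truth events
schedule_cohort <- function(run_seed, species = "HB_PLUS", n_specimens = 5, ...) {
  lapply(seq_len(n_specimens), function(k) {
    cfg <- sim_config(species, seed = as.integer(run_seed * 101 + k), ...)
    set.seed(cfg$seed)
    simulate_maneuver_schedule(cfg)$events
  })
}
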