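test_that("species parameter sets encode the documented contrasts", {
  cfgs <- default_species_configs()
  hbm <- cfgs$HB_MINUS; hbp <- cfgs$HB_PLUS
  # withdrawal-like maneuvers and their slow multi-stage C-bends are the
  # hemoglobinless repertoire; triplets and the lateral bias are Hb+ only
  expect_gt(max(hbm$maneuver_rates$WITHDRAWAL$rate), 0)
  expect_equal(max(hbm$triplet_rate$rate), 0)
  expect_equal(max(hbp$maneuver_rates$WITHDRAWAL$rate), 0)
  expect_gt(max(hbp$triplet_rate$rate), 0)
  expect_gt(hbp$bias_low, 0)
  expect_lt(hbp$bias_high, 0)
  expect_equal(hbm$bias_low, 0)
  # both species ramp at 3.2 degC/h; ventilation of Hb+ runs about twice as fast
  expect_equal(hbp$ramp_rate, 3.2)
  expect_equal(hbm$ramp_rate, 3.2)
  expect_gte(hbp$fv_base / hbm$fv_base, 1.8)
  expect_lt(hbm$speed_cap_bl_s, hbp$speed_cap_bl_s)
})

test_that("configs with out-of-band maneuver amplitudes are rejected", {
  expect_error(sim_config("HB_PLUS",
    va_bands = list(S_BEND = c(300, 400), C_BEND_SINGLE = c(110, 245),
                    C_BEND_MULTI = c(55, 85), WITHDRAWAL = c(25, 45))),
    "S_BEND")
  expect_error(sim_config("HB_MINUS",
    va_bands = list(S_BEND = c(620, 1000), C_BEND_SINGLE = c(110, 245),
                    C_BEND_MULTI = c(55, 120), WITHDRAWAL = c(25, 45))),
    "C_BEND_MULTI")
  expect_error(sim_config("HB_PLUS", bias_low = 1.5), "bias")
  expect_error(sim_config("HB_PLUS", nonsense_field = 1), "unknown")
})

test_that("the same seed reproduces the identical experiment; seeds differ", {
  cfg <- sim_config("HB_MINUS", seed = 31L, ramp_rate = 30, baseline_min = 2,
                    t_loe_fixed = 5.5)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$experiment$trajectory, b$experiment$trajectory)
  expect_identical(a$truth$events, b$truth$events)
  expect_identical(a$experiment$opercular$head_width,
                   b$experiment$opercular$head_width)
  cfg2 <- sim_config("HB_MINUS", seed = 32L, ramp_rate = 30, baseline_min = 2,
                     t_loe_fixed = 5.5)
  c_ <- simulate_experiment(cfg2)
  expect_false(identical(a$experiment$trajectory$com_x,
                         c_$experiment$trajectory$com_x))
})

test_that("zero event rates yield a quiet trajectory and an empty log", {
  zero <- list(temp = c(0, 20), rate = c(0, 0))
  cfg <- sim_config("HB_PLUS", seed = 33L, ramp_rate = 30, baseline_min = 2,
                    t_loe_fixed = 5.5, pos_noise_sd_cm = 0,
                    maneuver_rates = list(S_BEND = zero, C_BEND_SINGLE = zero,
                                          C_BEND_MULTI = zero, WITHDRAWAL = zero),
                    triplet_rate = zero)
  sim <- simulate_experiment(cfg, opercular = FALSE)
  expect_equal(nrow(sim$truth$events), 0)
  va <- angular_velocity(sim$experiment$trajectory)
  expect_lt(max(abs(va)), 20)
})

test_that("the ramp is monotone, ends at the drawn T_LOE, and T_LOE is sane", {
  sim <- battery_sim_clean()
  temp <- sim$experiment$trajectory$temp
  t <- sim$experiment$trajectory$t
  expect_true(all(diff(temp[t >= 0]) >= 0))
  expect_equal(max(temp), sim$truth$t_loe)
  cfg <- sim_config("HB_PLUS", seed = 7L)
  set.seed(cfg$seed)
  tl <- replicate(50, rampetho:::.draw_t_loe(cfg))
  expect_true(all(tl >= cfg$t0 + 5 & tl <= cfg$t0 + 20))
  expect_true(all(abs(tl - cfg$t_loe_mean) < 4 * cfg$t_loe_sd))
})

test_that("scheduled C-bend counts sit in the Poisson band of the rate integral", {
  cfg <- sim_config("HB_PLUS", seed = 7L,
                    triplet_rate = list(temp = c(0, 20), rate = c(0, 0)))
  set.seed(cfg$seed)
  sched <- simulate_maneuver_schedule(cfg)
  # brute-force integral of the configured rate curve over the ramp
  rate_fn <- rampetho:::.interp_curve(cfg$maneuver_rates$C_BEND_SINGLE)
  sec <- seq(0.5, sched$ramp_dur_s - 1, by = 1)
  temp_sec <- pmin(cfg$t0 + cfg$ramp_rate / 3600 * sec, sched$t_loe)
  lambda <- sum(rate_fn(temp_sec)) / 60
  n_cb <- sum(sched$events$klass == "C_BEND_SINGLE")
  expect_gte(n_cb, qpois(0.005, lambda))
  expect_lte(n_cb, qpois(0.995, lambda))
})

test_that("every scheduled event lies in the span and the log is exhaustive", {
  sim <- battery_sim_clean()
  ev <- sim$truth$events
  tr <- sim$experiment$trajectory
  expect_true(all(ev$t_onset > 0 & ev$t_onset + ev$span_s < max(tr$t)))
  # oracle equivalence at zero noise: detections and log are a bijection
  mp <- maneuver_pipeline(sim$experiment)
  expect_equal(nrow(mp$events), nrow(ev))
  m <- match_events(ev, mp$events)
  expect_equal(sort(m), seq_len(nrow(ev)))   # one detection per logged event
  expect_lt(max(abs(mp$events$t_onset[m] - ev$t_onset)), 0.2)
})

test_that("labriform travel respects the species speed cap", {
  sim <- battery_sim_clean()
  sp <- sim$experiment$specimen
  v <- instantaneous_velocity(sim$experiment$trajectory, sp)
  cap <- sim_config("HB_PLUS")$speed_cap_bl_s
  # outside maneuver windows the fish never exceeds the cap
  ev <- sim$truth$events
  in_event <- rep(FALSE, length(v))
  tt <- sim$experiment$trajectory$t
  for (i in seq_len(nrow(ev)))
    in_event <- in_event | (tt >= ev$t_onset[i] - 0.5 &
                              tt <= ev$t_onset[i] + ev$span_s[i] + 3.5)
  expect_lte(max(v[!in_event]), cap)
})

test_that("the opercular trace is quantized with truthful per-cycle metrics", {
  cfg <- sim_config("HB_MINUS", seed = 41L, op_noise_sd_mm = 0,
                    t_loe_fixed = 10, baseline_min = 10)
  vr <- simulate_ventilation_run(cfg)
  w <- vr$trace$head_width
  expect_true(all(abs(w / 0.5 - round(w / 0.5)) < 1e-9))
  # true ventilation frequency peaks at the configured peak temperature
  grid <- seq(cfg$t0, 10, by = 0.01)
  expect_equal(grid[which.max(vr$curves$fv(grid))], 8.25, tolerance = 0.01)
  # zero-noise extraction recovers the configured OA to the quantum
  cyc <- extract_cycles(vr$trace)
  tr_cyc <- vr$cycles
  m <- vapply(cyc$t_open_start, function(t0) which.min(abs(tr_cyc$t_start - t0)),
              integer(1))
  expect_lt(stats::median(abs(cyc$oa_mm - tr_cyc$oa_true[m])), 0.5 + 1e-9)
})
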