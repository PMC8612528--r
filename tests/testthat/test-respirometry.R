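test_that("cycle metrics follow their definitions on a constructed waveform", {
  # 250 Hz waveform: linear opening over 0.132 s to +4 mm, closing back;
  # full-open detection at the cycle maximum (open_fraction = 1)
  fr <- 250
  open_t <- 0.132; period <- 0.6
  tt <- seq(0, 6, by = 1 / fr)
  ph <- tt %% period
  w <- 30 + ifelse(ph <= open_t, 4 * ph / open_t,
                   4 * pmax(1 - (ph - open_t) / (period - open_t), 0))
  trace <- opercular_trace(tt, w, rep(5, length(tt)), frame_rate = fr)
  cfg <- default_config(); cfg$open_fraction <- 1; cfg$frame_rate <- fr
  cyc <- extract_cycles(trace, cfg)
  expect_gt(nrow(cyc), 5)
  expect_equal(stats::median(cyc$oa_mm), 4.0, tolerance = 1e-9)
  expect_equal(stats::median(cyc$ot_s), 0.132, tolerance = 1e-9)
  expect_equal(stats::median(cyc$ov_mm_s), 4 / 0.132, tolerance = 1e-6)
  # OV identity holds cycle by cycle
  expect_equal(cyc$ov_mm_s, cyc$oa_mm / cyc$ot_s)
})

test_that("a flat trace yields no cycles, with a warning", {
  trace <- opercular_trace(1:100 / 30, rep(30, 100), rep(5, 100))
  expect_warning(cyc <- extract_cycles(trace), "less than one")
  expect_equal(nrow(cyc), 0)
})

test_that("ventilation tallies count cycles per minute on a known sinusoid", {
  # 0.5 Hz sinusoid for 10 min = 30 cycles/min, 300 cycles
  fr <- 30
  tt <- seq(0, 600, by = 1 / fr)
  w <- 35 + 2 * sin(2 * pi * 0.5 * tt)
  trace <- opercular_trace(tt, round(w / 0.5) * 0.5, rep(5, length(tt)))
  cyc <- extract_cycles(trace)
  expect_lte(abs(nrow(cyc) - 300), 2)
  vent <- ventilation_series(cyc, trace)
  expect_true(all(abs(vent$fv - 30) <= 1))
  # an empty window reports zero frequency and undefined means
  w2 <- c(w[1:9000], rep(35, length(w) - 9000))
  trace2 <- opercular_trace(tt, round(w2 / 0.5) * 0.5, rep(5, length(tt)))
  vent2 <- ventilation_series(extract_cycles(trace2), trace2)
  expect_equal(vent2$fv[10], 0)
  expect_true(is.na(vent2$oa_mm[10]))
})

test_that("baseline normalization maps the baseline to one and is idempotent", {
  s <- data.frame(t_mid = seq(30, 570, by = 60),
                  fv = c(40, 40, 40, 60, 80, 100, 90, 70, 60, 50),
                  oa_mm = rep(4, 10), ot_s = rep(0.5, 10), ov_mm_s = rep(8, 10))
  norm <- normalize_to_initial(s, c(0, 180), cols = "fv")
  expect_equal(norm$fv[1:3], rep(1, 3))
  expect_equal(max(norm$fv), 2.5)
  again <- normalize_to_initial(norm, c(0, 180), cols = "fv")
  expect_equal(again$fv, norm$fv)
  flat <- normalize_to_initial(s, c(0, 180), cols = "oa_mm")
  expect_equal(flat$oa_mm, rep(1, 10))
  expect_error(normalize_to_initial(s, c(-100, -50)), "no records")
})

test_that("simulated ventilation recovers the programmed bell curve", {
  cfg <- sim_config("HB_PLUS", seed = 51L)
  vr <- simulate_ventilation_run(cfg)
  cyc <- extract_cycles(vr$trace)
  vent <- ventilation_series(cyc, vr$trace)
  nv <- normalize_to_initial(vent, vr$baseline_window)
  pk <- which.max(nv$fv)
  expect_lt(abs(nv$temp[pk] - cfg$fv_peak_t), 0.5)
  expect_lt(abs(max(nv$fv) - cfg$fv_fold) / cfg$fv_fold, 0.10)
  # opening amplitude rises monotonically overall; opening time is biphasic
  ramp <- nv$temp > cfg$t0 + 0.5
  expect_gt(stats::cor(nv$temp[ramp], nv$oa_mm[ramp], use = "complete.obs"), 0.8)
  ot_min_t <- nv$temp[which.min(nv$ot_s)]
  expect_lt(abs(ot_min_t - cfg$fv_peak_t), 1.5)
})

test_that("fin metrics compute bout frequencies and carry temperatures", {
  fins <- fin_events(c("FANNING_BOUT", "SPLAY", "SURFACING"),
                     t_start = c(0, 10, 20), t_end = c(8, 22, 24),
                     n_beats = c(8, NA, NA), temp = c(9, 13, 10))
  fm <- fin_metrics(fins)
  expect_equal(fm$fanning$freq_hz, 1.0)   # 8 beats over 8 s
  expect_equal(fm$splay$dur_s, 12)
  expect_equal(fm$splay$temp, 13)
  expect_equal(fm$surfacing$dur_s, 4)
  expect_equal(fm$counts$n, c(1L, 1L, 1L))
  none <- fin_metrics(fin_events())
  expect_equal(nrow(none$fanning), 0)
  expect_equal(nrow(none$splay), 0)
})

test_that("ventilation series correlate on the normalized thermal axis", {
  s1 <- data.frame(pct = 0:100, fv = 1 + 1.5 * exp(-((0:100 - 55) / 20)^2))
  expect_equal(ventilation_correlation(s1, s1), 1)
  s2 <- s1; s2$fv <- -s1$fv
  expect_equal(ventilation_correlation(s1, s2), -1)
  # two independent-noise realizations of the same underlying f_V(T)
  runs <- lapply(c(61L, 62L), function(s) {
    cfg <- sim_config("HB_MINUS", seed = s, t_loe_fixed = 13.8)
    vr <- simulate_ventilation_run(cfg)
    vent <- ventilation_series(extract_cycles(vr$trace), vr$trace)
    vent$pct <- percent_tloe(vent$temp, vr$t0, vr$t_loe)
    vent
  })
  expect_gt(ventilation_correlation(runs[[1]], runs[[2]]), 0.8)
})

test_that("programmed phase-locking yields sub-frame opercular lags", {
  sim <- hbp_sim_coupled()
  ex <- sim$experiment
  mp <- maneuver_pipeline(ex)
  cp <- coupling_profile(mp$events, ex$opercular, mp$kin)
  cut <- sim$truth$t_loe - sim_config("HB_PLUS")$coupling_loss_c
  below <- cp$bins[cp$bins$temp_lo + 1 <= cut, ]
  expect_gt(nrow(below), 4)
  expect_true(all(abs(below$mean_lag_frames) <= 1))
  # profiles normalized within [0, 1]
  for (p in cp$profiles) {
    expect_true(all(p$va_mean >= 0 & p$va_mean <= 1))
    expect_true(all(p$hw_mean >= -1e-9 & p$hw_mean <= 1 + 1e-9))
  }
  # a single-turn bin reproduces that turn with zero spread
  one <- cp$profiles[[which(cp$bins$n_turns == min(cp$bins$n_turns))[1]]]
  if (cp$bins$n_turns[which.min(cp$bins$n_turns)] == 1)
    expect_true(all(one$va_sd == 0))
})

test_that("without coupling the opercular lag is uniform over the cycle", {
  sim <- hbp_sim_decoupled()
  mp <- maneuver_pipeline(sim$experiment)
  cp <- coupling_profile(mp$events, sim$experiment$opercular, mp$kin)
  u <- cp$turns[!is.na(cp$turns$lag_s) & !is.na(cp$turns$period_s), ]
  expect_gt(nrow(u), 100)
  z <- pmin(pmax(u$lag_s / u$period_s, -0.5), 0.5)
  ks <- suppressWarnings(stats::ks.test(z, "punif", -0.5, 0.5))
  expect_gt(ks$p.value, 0.05)
})
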