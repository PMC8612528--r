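# build a kinematic series directly from a signed Va profile (deg/s)
kin_from_va <- function(va, fr = 30, v_lin = NULL, temp = 10) {
  n <- length(va)
  h <- -cumsum(va) / fr
  ks <- data.frame(t = seq_len(n) / fr, temp = rep(temp, n),
                   v_lin = if (is.null(v_lin)) rep(0, n) else v_lin,
                   heading = h, v_ang = va)
  attr(ks, "frame_rate") <- fr
  class(ks) <- c("kinematic_series", "data.frame")
  ks
}

traj_for <- function(kin, x = 40, y = 40) {
  n <- nrow(kin)
  h <- kin$heading * pi / 180
  trajectory(kin$t, kin$temp, rep(x, n), rep(y, n),
             rep(x, n) + 10 * cos(h), rep(y, n) + 10 * sin(h))
}

half_sine <- function(peak, dur, fr = 30) peak * sin(pi * seq_len(round(dur * fr)) / round(dur * fr))

test_that("turn detection applies hysteresis, a merge gap, and finds nothing in quiet data", {
  sp <- specimen("HB_PLUS", 36.91, 7.8)
  flat <- kin_from_va(rep(0, 300))
  expect_equal(nrow(detect_turns(flat, traj_for(flat), sp)), 0)
  # two pulses 0.3 s apart merge into one event
  va <- c(rep(0, 60), half_sine(150, 0.5), rep(0, 9), half_sine(150, 0.5), rep(0, 60))
  kin <- kin_from_va(va)
  ev <- detect_turns(kin, traj_for(kin), sp)
  expect_equal(nrow(ev), 1)
  expect_gte(ev$n_va_peaks[1], 2)
  # the same pulses 2 s apart stay separate
  va2 <- c(rep(0, 60), half_sine(150, 0.5), rep(0, 60), half_sine(150, 0.5), rep(0, 60))
  kin2 <- kin_from_va(va2)
  expect_equal(nrow(detect_turns(kin2, traj_for(kin2), sp)), 2)
})

test_that("detection recovers scheduled maneuvers at their logged onsets", {
  sim <- battery_sim_clean()
  mp <- maneuver_pipeline(sim$experiment)
  tr <- sim$truth$events
  expect_equal(nrow(mp$events), nrow(tr))
  m <- match_events(tr, mp$events)
  # onsets agree within the threshold-crossing delay of the slowest pulses
  expect_lt(max(abs(mp$events$t_onset[m] - tr$t_onset) * 30), 6)
  expect_lt(stats::median(abs(mp$events$t_onset[m] - tr$t_onset) * 30), 2)
})

test_that("the classification rule reproduces the class bands", {
  feats <- data.frame(
    peak_va = c(800, 180, -60, 30, 300),
    peak_va_abs = c(800, 180, 60, 30, 300),
    n_va_peaks = c(1, 1, 3, 1, 2),
    net_disp_bl = c(0.2, 0.1, 0, -0.1, 0.05)
  )
  got <- classify_maneuver(feats)
  expect_equal(got$klass, c("S_BEND", "C_BEND_SINGLE", "C_BEND_MULTI",
                            "WITHDRAWAL", "C_BEND_SINGLE"))
  expect_equal(got$direction, c("RIGHT", "RIGHT", "LEFT", "NONE", "RIGHT"))
  # the unassigned multi-peak band (100, 500] is flagged, not guessed
  expect_equal(got$band_ambiguous, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  # a slow event without backward displacement is not a withdrawal
  slow <- data.frame(peak_va = 30, peak_va_abs = 30, n_va_peaks = 1,
                     net_disp_bl = 0.01)
  expect_equal(classify_maneuver(slow)$klass, "C_BEND_SINGLE")
})

test_that("classifier is exact on clean synthetic maneuvers and robust to noise", {
  clean <- battery_sim_clean()
  mp <- maneuver_pipeline(clean$experiment)
  tr <- clean$truth$events
  expect_gte(nrow(tr), 200)
  expect_setequal(unique(tr$klass),
                  c("S_BEND", "C_BEND_SINGLE", "C_BEND_MULTI", "WITHDRAWAL"))
  m <- match_events(tr, mp$events)
  expect_equal(mp$events$klass[m], tr$klass)          # diagonal confusion
  turn <- tr$klass != "WITHDRAWAL"
  expect_equal(mp$events$direction[m][turn], tr$direction[turn])
  noisy <- battery_sim_noisy()
  mpn <- maneuver_pipeline(noisy$experiment)
  trn <- noisy$truth$events
  mn <- match_events(trn, mpn$events)
  ok <- abs(mpn$events$t_onset[mn] - trn$t_onset) < 0.5
  acc <- mean(ok & mpn$events$klass[mn] == trn$klass)
  expect_gte(acc, 0.95)
})

test_that("near-wall flagging uses a strict half-body-length cutoff", {
  tank <- tank_geometry(93, 93)
  sp <- specimen("HB_PLUS", 36.91, 7.8)
  bl <- sp$body_length
  ev <- data.frame(com_x = c(0.4 * bl, 0.6 * bl, 0.5 * bl), com_y = rep(46.5, 3))
  expect_equal(flag_near_wall(ev, tank, sp), c(TRUE, FALSE, FALSE))
})

test_that("turn tallies bin at 0.5 degC and conserve counts", {
  ev <- data.frame(
    klass = c("C_BEND_SINGLE", "C_BEND_SINGLE", "C_BEND_MULTI", "S_BEND",
              "C_BEND_SINGLE"),
    direction = c("RIGHT", "LEFT", "RIGHT", "RIGHT", "RIGHT"),
    near_wall = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    temp_onset = c(12.1, 12.3, 12.6, 12.2, 12.4)
  )
  tal <- tally_turns(ev)
  expect_equal(tal$bins$temp_lo, c(12.0, 12.5))
  expect_equal(tal$bins$n, c(2L, 1L))       # S-bend not a C-bend; wall excluded
  expect_equal(tal$excluded, 1L)
  expect_equal(sum(tal$bins$n) + tal$excluded, tal$total_cbend)
  all_wall <- ev; all_wall$near_wall <- TRUE
  tal2 <- tally_turns(all_wall)
  expect_equal(sum(tal2$bins$n), 0)
  expect_equal(tal2$excluded, tal2$total_cbend)
})

test_that("tallies on simulated data conserve against the ground-truth log", {
  sim <- battery_sim_clean()
  mp <- maneuver_pipeline(sim$experiment)
  tal <- tally_turns(mp$events)
  truth_cb <- sim$truth$events$klass %in% c("C_BEND_SINGLE", "C_BEND_MULTI")
  expect_equal(tal$total_cbend, sum(truth_cb))
  expect_equal(sum(tal$bins$n) + tal$excluded, sum(truth_cb))
  expect_equal(sum(tal$bins$n), sum(truth_cb & !sim$truth$events$near_wall))
})

test_that("the lateralization index honors its identities and bounds", {
  expect_equal(lateralization_index(10, 0), 100)
  expect_equal(lateralization_index(0, 7), -100)
  expect_equal(lateralization_index(3, 7), -40)
  expect_true(is.na(lateralization_index(0, 0)))
  set.seed(9)
  a <- rpois(50, 5); b <- rpois(50, 5)
  ok <- a + b > 0
  lr <- lateralization_index(a[ok], b[ok])
  expect_true(all(lr >= -100 & lr <= 100))
  expect_equal(lateralization_index(a[ok], b[ok]),
               -lateralization_index(b[ok], a[ok]))
})

test_that("the cohort laterality profile tests bins against random choice", {
  # five specimens, all fully rightward in one bin: degenerate but reported
  per <- lapply(1:5, function(i) lr_events(rep(12, 10), rep("RIGHT", 10)))
  prof <- laterality_profile(per)
  b <- prof[prof$pct_lo == 10, ]
  expect_equal(b$mean_lr, 100)
  expect_equal(b$sem_lr, 0)
  expect_true(b$degenerate)
  expect_lt(b$p, 1e-300)
  # two specimens at +-20: mean 0, t = 0, p = 1
  per2 <- list(lr_events(rep(22, 10), rep(c("RIGHT", "LEFT"), c(6, 4))),
               lr_events(rep(22, 10), rep(c("RIGHT", "LEFT"), c(4, 6))))
  prof2 <- laterality_profile(per2)
  b2 <- prof2[prof2$pct_lo == 20, ]
  expect_equal(b2$mean_lr, 0)
  expect_equal(b2$t, 0)
  expect_equal(b2$p, 1)
  # a bin with one defined specimen is reported but untested
  per3 <- list(lr_events(33, "RIGHT"), lr_events(77, "LEFT"))
  prof3 <- laterality_profile(per3)
  expect_false(prof3$tested[prof3$pct_lo == 30])
  expect_equal(prof3$n_specimens[prof3$pct_lo == 30], 1L)
})

test_that("a programmed bias reversal appears in the cohort profile", {
  per <- schedule_cohort(1)
  prof <- laterality_profile(per)
  tested <- prof[prof$tested & !prof$degenerate, ]
  pre <- tested[tested$pct_hi <= 65, ]
  post <- tested[tested$pct_lo >= 65, ]
  expect_true(any(pre$mean_lr > 0 & pre$p < 0.05))
  expect_true(any(post$mean_lr < 0 & post$p < 0.05))
  # the sign change falls at the programmed 65 %T_LOE reversal
  neg <- prof$pct_lo[which(prof$n_specimens >= 2 & prof$mean_lr < 0)]
  expect_lte(abs(min(neg) - 65), 5)
})

test_that("mirror reflection swaps left and right and negates every LR", {
  sim <- battery_sim_clean()
  ex <- sim$experiment
  mp <- maneuver_pipeline(ex)
  tr0 <- ex$trajectory
  L <- ex$tank$length
  mir <- trajectory(tr0$t, tr0$temp, tr0$com_x, L - tr0$com_y,
                    tr0$snout_x, L - tr0$snout_y, frame_rate = tr0$frame_rate)
  ex_m <- ramp_experiment(ex$specimen, ex$tank, mir, annotations = ex$annotations,
                          t0 = ex$t0, t_loe = ex$t_loe,
                          baseline_window = ex$baseline_window)
  mpm <- maneuver_pipeline(ex_m)
  expect_equal(nrow(mpm$events), nrow(mp$events))
  swap <- c(RIGHT = "LEFT", LEFT = "RIGHT", NONE = "NONE")
  expect_equal(mpm$events$direction, unname(swap[mp$events$direction]))
  expect_equal(mpm$events$klass, mp$events$klass)
  lr0 <- rampetho:::.specimen_lr_bins(mp$events)
  lr1 <- rampetho:::.specimen_lr_bins(mpm$events)
  def <- !is.na(lr0$lr)
  expect_equal(lr1$lr[def], -lr0$lr[def])
})

test_that("triplet matching is strict in order and glide requirements", {
  fr <- 30
  # one splay, then a C-turn 1 s after splay end, then a decaying glide
  va <- c(rep(0, 150), half_sine(180, 0.8), rep(0, 300))
  n <- length(va)
  v_lin <- rep(0.01, n)
  glide_i <- 172:240   # glide begins as the turn pulse ends
  v_lin[glide_i] <- seq(0.4, 0, length.out = length(glide_i))
  kin <- kin_from_va(va, v_lin = v_lin)
  sp <- specimen("HB_PLUS", 36.91, 7.8)
  evs <- classify_maneuver(detect_turns(kin, traj_for(kin), sp))
  expect_equal(evs$klass, "C_BEND_SINGLE")
  fins_ok <- fin_events("SPLAY", t_start = 2, t_end = 4)
  got <- detect_triplets(evs, fins_ok, kin)
  expect_equal(nrow(got), 1)
  # wrong order: splay after the turn matches nothing
  fins_late <- fin_events("SPLAY", t_start = 8, t_end = 9)
  expect_equal(nrow(detect_triplets(evs, fins_late, kin)), 0)
  # a fanning bout during the glide vetoes the triplet
  fins_fan <- fin_events(c("SPLAY", "FANNING_BOUT"), t_start = c(2, 6),
                         t_end = c(4, 8.5), n_beats = c(NA, 3))
  expect_equal(nrow(detect_triplets(evs, fins_fan, kin)), 0)
  # no glide (stationary after turn) also fails
  kin_still <- kin_from_va(va, v_lin = rep(0.01, n))
  expect_equal(nrow(detect_triplets(evs, fins_ok, kin_still)), 0)
})

test_that("simulated triplet sequences are recovered against the log", {
  sim <- hbp_sim_coupled()
  ex <- sim$experiment
  mp <- maneuver_pipeline(ex)
  trips <- detect_triplets(mp$events, ex$annotations, mp$kin)
  truth <- sim$truth$triplets
  expect_gt(nrow(truth), 20)
  # recovered count within 20% of the scheduled count
  expect_lt(abs(nrow(trips) - nrow(truth)) / nrow(truth), 0.2)
  m <- vapply(truth$t_turn, function(t0) min(abs(trips$t_turn - t0)), numeric(1))
  expect_gt(mean(m < 0.5), 0.8)
})
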