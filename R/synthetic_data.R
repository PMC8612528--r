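#' Synthetic thermal-ramp experiments with ground truth
#'
#' Generates complete `ramp_experiment` objects — 30 Hz trajectory, opercular
#' head-width trace, fin/surface annotations — together with an exhaustive
#' ground-truth log of every scheduled event and every underlying parameter
#' curve. The generator emulates the statistical structure the analysis
#' assumes (a ~3.2 degC/h ramp to a species-dependent T_LOE, alternating
#' locomotor phases, four maneuver classes in their angular-velocity bands,
#' a rightward-then-leftward laterality bias with a reversal point, a
#' bell-shaped ventilation-frequency curve with monotone-rising opening
#' amplitude and biphasic opening time, thermally windowed fin behaviors, and
#' Splay-Turn-Glide triplets with opercular phase-locking), not hydrodynamics.
#'
#' @name synthetic_data
NULL

.interp_curve <- function(curve) {
  force(curve)
  function(temp) {
    y <- stats::approx(curve$temp, curve$rate, xout = temp, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
}

#' Simulation configuration
#'
#' Builds a validated configuration for [simulate_experiment()]. Call with a
#' species to start from [default_species_configs()] and override fields.
#'
#' @param species `"HB_PLUS"` or `"HB_MINUS"`.
#' @param ... overrides of any default field (see Details).
#' @details Fields include `seed`, `ramp_rate` (degC/h, 3.2), `t0` (degC),
#'   `t_loe_mean`/`t_loe_sd` (degC), `t_loe_fixed` (optional: skip the draw),
#'   `baseline_min` (min), `frame_rate` (Hz), `tank`, `body_length`/
#'   `body_width` (cm), `speed_cap_bl_s`, `maneuver_rates` (per-class
#'   rate-vs-temperature curves, events/min), `va_bands` (deg/s per class),
#'   `cmulti_pulses`, `withdrawal_disp_bl`, `bias_low`/`bias_high`/
#'   `reversal_pct` (laterality), `pos_noise_sd_cm`, `dropout_rate`,
#'   ventilation fields (`fv_base`, `fv_peak_t`, `fv_fold`, `oa_base_mm`,
#'   `oa_fold_loe`, `ot_frac`, `op_noise_sd_mm`, `fv_jitter_cv`), `coupling`,
#'   `coupling_loss_c`, `triplet_rate` curve, and fin-behavior curves
#'   (`fanning_rate`, `fanning_dur_s`, `fanning_freq_hz`, `splay_rate`,
#'   `splay_dur_s`, `surfacing_rate`, `surfacing_dur_s`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(species = c("HB_PLUS", "HB_MINUS"), ...) {
  species <- match.arg(species)
  cfg <- default_species_configs()[[species]]
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_sim_config(cfg)
  cfg
}

.validate_sim_config <- function(cfg) {
  stopifnot(cfg$ramp_rate > 0, cfg$t_loe_sd >= 0, cfg$frame_rate > 0)
  if (abs(cfg$bias_low) > 1 || abs(cfg$bias_high) > 1)
    stop("laterality bias must lie in [-1, 1]")
  if (cfg$reversal_pct <= 0 || cfg$reversal_pct >= 100)
    stop("reversal_pct must lie strictly between 0 and 100 %T_LOE")
  for (k in names(cfg$maneuver_rates)) {
    if (any(cfg$maneuver_rates[[k]]$rate < 0)) stop("negative maneuver rate for ", k)
  }
  b <- cfg$va_bands
  if (b$S_BEND[1] <= 500)
    stop("S_BEND Va band inconsistent with its class (must exceed 500 deg/s)")
  if (b$C_BEND_SINGLE[1] <= 100 || b$C_BEND_SINGLE[2] > 500)
    stop("C_BEND_SINGLE Va band inconsistent with its class ((100, 500] deg/s)")
  if (b$C_BEND_MULTI[2] >= 100)
    stop("C_BEND_MULTI Va band inconsistent with its class (below 100 deg/s)")
  if (b$WITHDRAWAL[2] >= 50)
    stop("WITHDRAWAL Va band inconsistent with its class (below 50 deg/s)")
  invisible(cfg)
}

#' Default per-species simulation parameter sets
#'
#' Two documented parameter sets reproducing the qualitative species
#' contrasts: the hemoglobin-expressing morph (HB_PLUS) is more agile
#' (speed cap 0.8 BL/s), ventilates about twice as fast, performs fast
#' S-bends and single-stage C-bends with a rightward-then-leftward turning
#' bias reversing at 65 %T_LOE, and produces Splay-Turn-Glide triplets with
#' respiratory-locomotor coupling; the hemoglobinless morph (HB_MINUS) is
#' slower (0.4 BL/s), performs sporadic multi-stage C-bends and — uniquely —
#' withdrawal-like maneuvers, with no turning bias, no triplets and no
#' coupling. Both ramp at 3.2 degC/h.
#'
#' @return named list with `HB_PLUS` and `HB_MINUS` `sim_config`s.
#' @export
default_species_configs <- function() {
  common <- list(
    seed = 1L, frame_rate = 30, ramp_rate = 3.2, t0 = 0.5,
    t_loe_fixed = NULL, baseline_min = 60, tank = tank_geometry(),
    pos_noise_sd_cm = 0.05, dropout_rate = 0.001,
    min_event_gap_s = 4, snout_offset_bl = 0.35,
    heading_drift_sd = 0.02,
    va_bands = list(S_BEND = c(620, 1000), C_BEND_SINGLE = c(110, 245),
                    C_BEND_MULTI = c(55, 85), WITHDRAWAL = c(25, 45)),
    cmulti_pulses = 2:4, withdrawal_disp_bl = c(0.08, 0.15),
    fv_peak_t = 8.25, oa_base_mm = 4, oa_fold_loe = 2, ot_frac = 0.45,
    op_noise_sd_mm = 0.15, fv_jitter_cv = 0.02, coupling_loss_c = 1,
    surfacing_rate = list(temp = c(6, 8, 12), rate = c(0, 0.3, 0)),
    surfacing_dur_s = c(2, 8)
  )
  hbp <- c(common, list(
    species = "HB_PLUS", t_loe_mean = 15.8, t_loe_sd = 0.9,
    body_length = 36.91, body_width = 7.8, speed_cap_bl_s = 0.8,
    maneuver_rates = list(
      S_BEND = list(temp = c(9.5, 10.5, 12), rate = c(0, 0.12, 0)),
      C_BEND_SINGLE = list(temp = c(6, 7, 10, 12, 14, 15.3, 15.8),
                           rate = c(0, 1, 2.5, 4, 4, 1, 0.5)),
      C_BEND_MULTI = list(temp = c(0, 20), rate = c(0, 0)),
      WITHDRAWAL = list(temp = c(0, 20), rate = c(0, 0))
    ),
    bias_low = 0.8, bias_high = -0.8, reversal_pct = 65,
    fv_base = 30, fv_fold = 2.5, fv_post = "decline",
    coupling = TRUE,
    triplet_rate = list(temp = c(11.5, 12.5, 14, 15, 15.5),
                        rate = c(0, 5, 6, 2, 0)),
    fanning_rate = list(temp = c(8, 9, 13, 15.8), rate = c(0, 0.3, 0.6, 0.3)),
    fanning_dur_s = c(3, 10), fanning_freq_hz = c(0.35, 0.5),
    splay_rate = list(temp = c(10, 13, 16), rate = c(0.2, 2, 1)),
    splay_dur_s = c(2, 4), splay_dur_fold = 5
  ))
  hbm <- c(common, list(
    species = "HB_MINUS", t_loe_mean = 13.8, t_loe_sd = 0.9,
    body_length = 47.36, body_width = 5.65, speed_cap_bl_s = 0.4,
    maneuver_rates = list(
      S_BEND = list(temp = c(0, 20), rate = c(0, 0)),
      C_BEND_SINGLE = list(temp = c(0, 20), rate = c(0, 0)),
      C_BEND_MULTI = list(temp = c(4, 5, 13.8), rate = c(0, 0.25, 0.25)),
      WITHDRAWAL = list(temp = c(9, 10, 12, 12.5), rate = c(0, 0.4, 0.4, 0))
    ),
    bias_low = 0, bias_high = 0, reversal_pct = 65,
    fv_base = 16, fv_fold = 2.61, fv_post = "plateau",
    coupling = FALSE,
    triplet_rate = list(temp = c(0, 20), rate = c(0, 0)),
    fanning_rate = list(temp = c(8, 9, 13.8), rate = c(0, 0.4, 0.7)),
    fanning_dur_s = c(20, 150), fanning_freq_hz = c(0.8, 1.2),
    splay_rate = list(temp = c(9, 11, 13), rate = c(0.1, 0.4, 0.3)),
    splay_dur_s = c(2, 4), splay_dur_fold = 3
  ))
  lapply(list(HB_PLUS = hbp, HB_MINUS = hbm), function(x) {
    class(x) <- c("sim_config", "list"); x
  })
}

# Draw the loss-of-equilibrium temperature: normal, clipped to [t0+5, t0+20].
.draw_t_loe <- function(cfg) {
  if (!is.null(cfg$t_loe_fixed)) return(cfg$t_loe_fixed)
  min(max(stats::rnorm(1, cfg$t_loe_mean, cfg$t_loe_sd), cfg$t0 + 5), cfg$t0 + 20)
}

# Inhomogeneous-Poisson event times from a rate-vs-temperature curve
# (events/min), on a 1-s grid over the ramp.
.draw_event_times <- function(t_end, temp_of, rate_curve) {
  sec <- seq(0.5, t_end - 1, by = 1)
  lam <- .interp_curve(rate_curve)(temp_of(sec)) / 60
  n <- stats::rpois(length(sec), lam)
  keep <- n > 0
  if (!any(keep)) return(numeric(0))
  sort(rep(sec[keep], n[keep]) + stats::runif(sum(n), -0.5, 0.5))
}

.fold_coord <- function(x, lo, hi) {
  p <- hi - lo
  y <- (x - lo) %% (2 * p)
  ifelse(y > p, 2 * p - y, y) + lo
}

#' Draw the maneuver and fin-event schedule of one experiment
#'
#' The scheduling layer of the simulator: draws T_LOE, event times from the
#' per-class rate-vs-temperature curves, turn directions from the laterality
#' bias (with its reversal at `reversal_pct` %T_LOE), per-event
#' angular-velocity amplitudes within the class bands, anchor positions in
#' the tank, and the fin/surface/triplet event streams. [simulate_experiment()]
#' realizes this schedule as traces; the schedule alone is the ground truth
#' for count-, laterality- and rate-level analyses.
#'
#' @param cfg a `sim_config`.
#' @param t_loe optional pre-drawn T_LOE (degC); drawn from the config
#'   otherwise. Note: the caller must have seeded the RNG (or set
#'   `cfg$seed` and call via [simulate_experiment()]).
#' @return list with `t_loe`, `ramp_dur_s`, `events` (maneuver schedule),
#'   `fins` (fin-event schedule), `triplets`.
#' @export
simulate_maneuver_schedule <- function(cfg, t_loe = NULL) {
  if (is.null(t_loe)) t_loe <- .draw_t_loe(cfg)
  ramp_dur <- (t_loe - cfg$t0) / cfg$ramp_rate * 3600
  temp_of <- function(t) pmin(cfg$t0 + cfg$ramp_rate / 3600 * pmax(t, 0), t_loe)
  bl <- cfg$body_length
  tank <- cfg$tank

  classes <- c("S_BEND", "C_BEND_SINGLE", "C_BEND_MULTI", "WITHDRAWAL")
  ev <- do.call(rbind, lapply(classes, function(k) {
    tt <- .draw_event_times(ramp_dur, temp_of, cfg$maneuver_rates[[k]])
    if (!length(tt)) return(NULL)
    data.frame(klass = k, t_sched = tt, triplet = FALSE)
  }))
  # triplet turns are additional single-stage C-bends
  tt <- .draw_event_times(ramp_dur, temp_of, cfg$triplet_rate)
  if (length(tt))
    ev <- rbind(ev, data.frame(klass = "C_BEND_SINGLE", t_sched = tt, triplet = TRUE))
  if (is.null(ev) || !nrow(ev)) {
    ev <- data.frame(klass = character(0), t_sched = numeric(0), triplet = logical(0))
  }
  ev <- ev[order(ev$t_sched), , drop = FALSE]
  n <- nrow(ev)

  # per-event kinematic parameters
  band <- function(k) cfg$va_bands[[k]]
  peak_va <- numeric(n); dur <- numeric(n); n_pulses <- integer(n)
  back_disp <- numeric(n)
  for (i in seq_len(n)) {
    b <- band(ev$klass[i])
    peak_va[i] <- stats::runif(1, b[1], b[2])
    n_pulses[i] <- 1L
    dur[i] <- switch(ev$klass[i],
      S_BEND = stats::runif(1, 0.15, 0.2),
      C_BEND_SINGLE = stats::runif(1, 0.7, 1.2),
      C_BEND_MULTI = stats::runif(1, 0.5, 0.8),
      WITHDRAWAL = stats::runif(1, 0.8, 1.2))
    if (ev$klass[i] == "C_BEND_MULTI")
      n_pulses[i] <- sample(cfg$cmulti_pulses, 1)
    if (ev$klass[i] == "WITHDRAWAL")
      back_disp[i] <- stats::runif(1, cfg$withdrawal_disp_bl[1], cfg$withdrawal_disp_bl[2])
  }
  # total event span: multi-stage C-bends are n pulses with 0.25 s gaps;
  # triplet turns also own a post-turn glide window (up to 3 s)
  span <- dur + (n_pulses - 1) * (dur + 0.25)
  span_eff <- span + ifelse(ev$triplet, 3, 0)

  # enforce separation by pushing conflicting events later (counts preserved);
  # events pushed past the ramp end are dropped
  if (n > 1) {
    last_end <- ev$t_sched[1] + span_eff[1]
    for (i in 2:n) {
      if (ev$t_sched[i] < last_end + cfg$min_event_gap_s)
        ev$t_sched[i] <- last_end + cfg$min_event_gap_s
      last_end <- ev$t_sched[i] + span_eff[i]
    }
  }
  keep <- ev$t_sched + span_eff < ramp_dur - 5
  ev <- ev[keep, , drop = FALSE]
  peak_va <- peak_va[keep]; dur <- dur[keep]; n_pulses <- n_pulses[keep]
  back_disp <- back_disp[keep]; span <- span[keep]; span_eff <- span_eff[keep]
  n <- nrow(ev)

  # time the fish must stay on station after an event onset (span, a possible
  # glide, and a small buffer) before traveling to the next anchor
  hold_after <- span_eff + 0.5

  temp_onset <- temp_of(ev$t_sched)
  pct <- percent_tloe(temp_onset, cfg$t0, t_loe)
  bias <- ifelse(pct < cfg$reversal_pct, cfg$bias_low, cfg$bias_high)
  turn_like <- ev$klass != "WITHDRAWAL"
  direction <- rep("NONE", n)
  if (any(turn_like))
    direction[turn_like] <- ifelse(
      stats::runif(sum(turn_like)) < (1 + bias[turn_like]) / 2, "RIGHT", "LEFT")
  # withdrawal head rotation still has a (random) sign
  rot_sign <- ifelse(direction == "RIGHT", 1,
                     ifelse(direction == "LEFT", -1, sample(c(-1, 1), n, TRUE)))

  # anchor positions: a reachable random walk folded into the tank; events in
  # triplets or with backward displacement are kept in the interior so glides
  # and retractions stay in bounds
  margin <- 1.5
  interior <- c(0.25, 0.75)
  ax <- numeric(n); ay <- numeric(n)
  if (n) {
    ax[1] <- stats::runif(1, margin, tank$width - margin)
    ay[1] <- stats::runif(1, margin, tank$length - margin)
    gaps <- diff(c(0, ev$t_sched))
    cap_cm <- cfg$speed_cap_bl_s * bl
    for (i in seq_len(n)) {
      if (i > 1) {
        reach <- 0.45 * cap_cm * max(gaps[i] - hold_after[i - 1] - 1.5, 0.5)
        step <- stats::rnorm(2, 0, 25)
        nr <- sqrt(sum(step^2))
        if (nr > reach) step <- step * reach / nr
        ax[i] <- .fold_coord(ax[i - 1] + step[1], margin, tank$width - margin)
        ay[i] <- .fold_coord(ay[i - 1] + step[2], margin, tank$length - margin)
      }
      if (ev$triplet[i] || ev$klass[i] == "WITHDRAWAL") {
        ax[i] <- min(max(ax[i], interior[1] * tank$width), interior[2] * tank$width)
        ay[i] <- min(max(ay[i], interior[1] * tank$length), interior[2] * tank$length)
      }
    }
  }
  near_wall <- wall_distance(tank, ax, ay) < 0.5 * bl

  events <- data.frame(
    klass = ev$klass, direction = direction, triplet = ev$triplet,
    t_onset = ev$t_sched, span_s = span, dur_s = dur, n_pulses = n_pulses,
    peak_va = peak_va, rot_sign = rot_sign, back_disp_bl = back_disp,
    hold_after_s = hold_after,
    anchor_x = ax, anchor_y = ay, near_wall = near_wall,
    temp_onset = temp_onset, pct_tloe = pct
  )

  # fin events -----------------------------------------------------------
  draw_bouts <- function(kind, rate_curve, dur_range, fold = 1) {
    tt <- .draw_event_times(ramp_dur, temp_of, rate_curve)
    if (!length(tt)) return(NULL)
    dmax <- dur_range[2] * ifelse(fold > 1,
      1 + (fold - 1) * pmin(pmax(percent_tloe(temp_of(tt), cfg$t0, t_loe), 0), 100) / 100, 1)
    d <- stats::runif(length(tt), dur_range[1], dmax)
    data.frame(kind = kind, t_start = tt, t_end = tt + d)
  }
  fan <- draw_bouts("FANNING_BOUT", cfg$fanning_rate, cfg$fanning_dur_s)
  spl <- draw_bouts("SPLAY", cfg$splay_rate, cfg$splay_dur_s, cfg$splay_dur_fold)
  srf <- draw_bouts("SURFACING", cfg$surfacing_rate, cfg$surfacing_dur_s)
  if (!is.null(fan))
    fan$n_beats <- pmax(1, round(stats::runif(nrow(fan), cfg$fanning_freq_hz[1],
                                              cfg$fanning_freq_hz[2]) *
                                   (fan$t_end - fan$t_start)))

  # triplet realization: a splay ending shortly before each triplet turn,
  # and a glide after it; fanning bouts overlapping the glide are dropped
  trip_idx <- which(events$triplet)
  triplets <- NULL
  if (length(trip_idx)) {
    gap1 <- stats::runif(length(trip_idx), 0.3, 2)
    sdur <- stats::runif(length(trip_idx), cfg$splay_dur_s[1], cfg$splay_dur_s[2])
    glide_dur <- stats::runif(length(trip_idx), 1, 2.5)
    tr_spl <- data.frame(kind = "SPLAY",
                         t_start = events$t_onset[trip_idx] - gap1 - sdur,
                         t_end = events$t_onset[trip_idx] - gap1)
    triplets <- data.frame(
      t_splay_start = tr_spl$t_start, t_splay_end = tr_spl$t_end,
      t_turn = events$t_onset[trip_idx],
      t_glide_start = events$t_onset[trip_idx] + events$span_s[trip_idx],
      glide_dur_s = glide_dur,
      temp = events$temp_onset[trip_idx]
    )
    spl <- rbind(spl, tr_spl[, c("kind", "t_start", "t_end")])
    if (!is.null(fan)) {
      guard_lo <- events$t_onset[trip_idx] - 5
      guard_hi <- events$t_onset[trip_idx] + events$span_s[trip_idx] + glide_dur + 1
      bad <- vapply(seq_len(nrow(fan)), function(i)
        any(fan$t_start[i] < guard_hi & fan$t_end[i] > guard_lo), logical(1))
      fan <- fan[!bad, , drop = FALSE]
    }
  }
  fins <- fin_events()
  parts <- list(fan, spl, srf)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (length(parts)) {
    allf <- do.call(rbind, lapply(parts, function(p) {
      p$n_beats <- if ("n_beats" %in% names(p)) p$n_beats else NA_real_
      p[, c("kind", "t_start", "t_end", "n_beats")]
    }))
    allf <- allf[allf$t_start > 0 & allf$t_end < ramp_dur, , drop = FALSE]
    allf <- allf[order(allf$t_start), , drop = FALSE]
    fins <- fin_events(allf$kind, allf$t_start, allf$t_end, n_beats = allf$n_beats,
                       temp = temp_of(allf$t_start))
  }
  list(t_loe = t_loe, ramp_dur_s = ramp_dur, events = events, fins = fins,
       triplets = triplets)
}

# Half-sine angular-velocity pulse(s) of one maneuver, added onto `va` in place.
.add_va_pulses <- function(va, t, onset, dur, n_pulses, peak, sgn) {
  start <- onset
  for (p in seq_len(n_pulses)) {
    i <- which(t >= start & t <= start + dur)
    if (length(i))
      va[i] <- va[i] + sgn * peak * sin(pi * (t[i] - start) / dur)
    start <- start + dur + 0.25
  }
  va
}

#' Simulate a complete ramp experiment
#'
#' Realizes a drawn schedule (see [simulate_maneuver_schedule()]) as a 30 Hz
#' trajectory: a baseline hour of station-holding, alternating travel legs
#' (labriform-speed, at most the species speed cap) and station-holding
#' between maneuver anchors, maneuvers as half-sine angular-velocity pulses
#' on the heading channel (multi-stage C-bends as 2-4 superposed low pulses,
#' withdrawals as a low pulse plus a backward center-of-mass displacement),
#' glides after triplet turns, additive Gaussian positional jitter, and a
#' linear temperature ramp ending exactly at the drawn T_LOE. The same seed
#' always reproduces the identical experiment.
#'
#' @param cfg a `sim_config`.
#' @param opercular also synthesize the opercular trace (default TRUE).
#' @return list with `experiment` (a `ramp_experiment`) and `truth`
#'   (the ground-truth log: `events`, `fins`, `triplets`, `t_loe`, `seed`,
#'   and — when `opercular` — `cycles` and `ventilation_curves`).
#' @export
simulate_experiment <- function(cfg, opercular = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  .validate_sim_config(cfg)
  set.seed(cfg$seed)
  sched <- simulate_maneuver_schedule(cfg)
  fr <- cfg$frame_rate
  t <- seq(-cfg$baseline_min * 60, sched$ramp_dur_s, by = 1 / fr)
  n <- length(t)
  temp <- pmin(cfg$t0 + cfg$ramp_rate / 3600 * pmax(t, 0), sched$t_loe)
  temp[length(temp)] <- sched$t_loe
  bl <- cfg$body_length
  ev <- sched$events

  # heading: slow smoothed drift + maneuver pulses
  drift <- smooth_series(stats::rnorm(n, 0, cfg$heading_drift_sd), 15)
  va <- numeric(n)
  for (i in seq_len(nrow(ev)))
    va <- .add_va_pulses(va, t, ev$t_onset[i], ev$dur_s[i], ev$n_pulses[i],
                         ev$peak_va[i], ev$rot_sign[i])
  heading <- stats::runif(1, 0, 360) + cumsum(drift) - cumsum(va) / fr

  # center of mass: hold at each anchor, travel between anchors, and hold
  # (with tiny drift) through the baseline hour
  com_x <- numeric(n); com_y <- numeric(n)
  start_xy <- c(cfg$tank$width / 2, cfg$tank$length / 2)
  if (nrow(ev)) {
    nodes_t <- ev$t_onset
    nodes_x <- ev$anchor_x
    nodes_y <- ev$anchor_y
  } else {
    nodes_t <- numeric(0); nodes_x <- numeric(0); nodes_y <- numeric(0)
  }
  # piecewise: before first anchor hold at start; between consecutive anchors
  # travel during the middle of the gap at sub-cap speed
  nodes_t <- c(t[1], nodes_t, t[n])
  nodes_x <- c(start_xy[1], nodes_x, if (length(nodes_x)) nodes_x[length(nodes_x)] else start_xy[1])
  nodes_y <- c(start_xy[2], nodes_y, if (length(nodes_y)) nodes_y[length(nodes_y)] else start_xy[2])
  # station time owed after each node (event span + glide + buffer)
  nodes_hold <- c(0, if (nrow(ev)) ev$hold_after_s else numeric(0), 0)
  cap_cm <- cfg$speed_cap_bl_s * bl
  for (k in seq_len(length(nodes_t) - 1)) {
    i0 <- findInterval(nodes_t[k], t); i1 <- findInterval(nodes_t[k + 1], t)
    seg <- i0:i1
    d <- sqrt((nodes_x[k + 1] - nodes_x[k])^2 + (nodes_y[k + 1] - nodes_y[k])^2)
    if (d < 1e-9) { com_x[seg] <- nodes_x[k]; com_y[seg] <- nodes_y[k]; next }
    gap <- nodes_t[k + 1] - nodes_t[k]
    avail <- max(gap - nodes_hold[k] - 1, 0.2)
    # smooth-step peak speed is 1.5 * d / travel; keep it at or under 0.9 cap
    travel <- min(max(d / (0.6 * cap_cm), min(2, avail)), avail)
    t_dep <- nodes_t[k] + nodes_hold[k] + max((avail - travel) / 2, 0)
    t_arr <- min(t_dep + travel, nodes_t[k + 1])
    frac <- (t[seg] - t_dep) / max(t_arr - t_dep, 1e-9)
    frac <- pmin(pmax(frac, 0), 1)
    s <- frac * frac * (3 - 2 * frac)
    com_x[seg] <- nodes_x[k] + (nodes_x[k + 1] - nodes_x[k]) * s
    com_y[seg] <- nodes_y[k] + (nodes_y[k + 1] - nodes_y[k]) * s
  }
  # withdrawal retractions and triplet glides are local excursions from the
  # station anchor: the displacement builds during the event and then drifts
  # back to the anchor before the next travel leg, so anchors stay exact
  add_excursion <- function(t_from, t_to, profile_fn, h0, amp) {
    j <- which(t >= t_from & t <= t_to)
    if (length(j) < 2) return(invisible())
    disp <- amp * profile_fn((t[j] - t_from) / (t_to - t_from))
    # drift back over up to 2.5 s after the excursion
    jb <- which(t > t_to & t <= t_to + 2.5)
    ux <- cos(h0); uy <- sin(h0)
    com_x[j] <<- com_x[j] + disp * ux
    com_y[j] <<- com_y[j] + disp * uy
    if (length(jb)) {
      back <- amp * (1 - (t[jb] - t_to) / (t[jb[length(jb)]] - t_to))
      com_x[jb] <<- com_x[jb] + back * ux
      com_y[jb] <<- com_y[jb] + back * uy
    }
    invisible()
  }
  for (i in seq_len(nrow(ev))) {
    if (ev$klass[i] == "WITHDRAWAL") {
      i_on <- findInterval(ev$t_onset[i], t)
      h0 <- heading[i_on] * pi / 180
      add_excursion(ev$t_onset[i], ev$t_onset[i] + 1.2,
                    function(p) (1 - cos(pi * p)) / 2,
                    h0 + pi, ev$back_disp_bl[i] * bl)
    }
  }
  if (!is.null(sched$triplets)) {
    tr <- sched$triplets
    for (i in seq_len(nrow(tr))) {
      i_on <- findInterval(tr$t_glide_start[i], t)
      h0 <- heading[i_on] * pi / 180
      gd <- tr$glide_dur_s[i]
      v0 <- 0.45 * cap_cm
      room <- max(wall_distance(cfg$tank, com_x[i_on], com_y[i_on]) - 1, 1)
      amp <- min(v0 * gd / 2, room)
      # linear speed decay v0 -> 0 over the glide
      add_excursion(tr$t_glide_start[i], tr$t_glide_start[i] + gd,
                    function(p) 2 * p - p^2, h0, amp)
    }
  }
  # clamp to the tank (numerical safety; displacements are planned in bounds)
  com_x <- pmin(pmax(com_x, 0.5), cfg$tank$width - 0.5)
  com_y <- pmin(pmax(com_y, 0.5), cfg$tank$length - 0.5)

  hrad <- heading * pi / 180
  snout_x <- com_x + cfg$snout_offset_bl * bl * cos(hrad)
  snout_y <- com_y + cfg$snout_offset_bl * bl * sin(hrad)
  if (cfg$pos_noise_sd_cm > 0) {
    com_x <- com_x + stats::rnorm(n, 0, cfg$pos_noise_sd_cm)
    com_y <- com_y + stats::rnorm(n, 0, cfg$pos_noise_sd_cm)
    snout_x <- snout_x + stats::rnorm(n, 0, cfg$pos_noise_sd_cm)
    snout_y <- snout_y + stats::rnorm(n, 0, cfg$pos_noise_sd_cm)
    com_x <- pmin(pmax(com_x, 0), cfg$tank$width)
    com_y <- pmin(pmax(com_y, 0), cfg$tank$length)
  }

  traj <- trajectory(t, temp, com_x, com_y, snout_x, snout_y, frame_rate = fr)
  spec <- specimen(cfg$species, cfg$body_length, cfg$body_width)

  # ground-truth event log in analysis coordinates
  ev$t_peak <- ev$t_onset + ev$dur_s / 2
  ev$seed <- rep(cfg$seed, nrow(ev))

  truth <- list(events = ev, fins = sched$fins, triplets = sched$triplets,
                t_loe = sched$t_loe, t0 = cfg$t0, seed = cfg$seed)

  op <- NULL
  if (opercular) {
    sim_op <- simulate_opercular(cfg, t, temp, t_loe = sched$t_loe,
                                 turn_peaks = ev$t_peak[ev$klass == "C_BEND_SINGLE"])
    op <- sim_op$trace
    truth$cycles <- sim_op$cycles
    truth$ventilation_curves <- sim_op$curves
  }

  experiment <- ramp_experiment(
    specimen = spec, tank = cfg$tank, trajectory = traj, opercular = op,
    annotations = sched$fins, t0 = cfg$t0, t_loe = sched$t_loe,
    baseline_window = c(t[1], 0)
  )
  list(experiment = experiment, truth = truth)
}

# Piecewise-linear fold curves of the ventilation parameters vs temperature.
.ventilation_curves <- function(cfg, t_loe) {
  t0 <- cfg$t0; pk <- cfg$fv_peak_t
  if (identical(cfg$fv_post, "decline")) {
    fv_anchor <- list(temp = c(t0, t0 + 0.5, t0 + 2, pk, pk + 2, t_loe - 1.5, t_loe),
                      rate = c(1, 1.15, 1.2, cfg$fv_fold, 1.5, 1.5, 0.8))
    ot_anchor <- list(temp = c(t0, pk, pk + 2, t_loe - 1.5, t_loe),
                      rate = c(1, 0.6, 0.85, 0.9, 1.1))
    oa_anchor <- list(temp = c(t0, 7, pk, t_loe),
                      rate = c(1, 1.05, 1.3, cfg$oa_fold_loe))
  } else {
    fv_anchor <- list(temp = c(t0, t0 + 0.5, t0 + 2, pk, t_loe - 1.25, t_loe),
                      rate = c(1, 1.1, 1.15, cfg$fv_fold, cfg$fv_fold * 0.95, 0.9))
    ot_anchor <- list(temp = c(t0, pk, t_loe - 1.25, t_loe),
                      rate = c(1, 0.6, 0.65, 0.85))
    oa_anchor <- list(temp = c(t0, t0 + 2, pk, t_loe),
                      rate = c(1, 1.1, 1.5, cfg$oa_fold_loe))
  }
  clampf <- function(anchor) {
    f <- stats::approxfun(anchor$temp, anchor$rate, rule = 2)
    function(temp) f(temp)
  }
  list(
    fv = function(temp) cfg$fv_base * clampf(fv_anchor)(temp),
    oa = function(temp) cfg$oa_base_mm * clampf(oa_anchor)(temp),
    ot = function(temp) cfg$ot_frac * 60 / cfg$fv_base * clampf(ot_anchor)(temp),
    peak_t = pk
  )
}

#' Simulate an opercular head-width trace
#'
#' A quasi-sinusoidal head-width signal whose instantaneous cycle rate
#' follows the configured f_V(T) (bell-shaped to a peak at `fv_peak_t`, then
#' a species-specific plateau or decline), whose amplitude follows the
#' monotone-rising OA(T), and whose opening time follows the biphasic OT(T).
#' Each cycle opens along a half-cosine for OT seconds and closes for the
#' rest of the period, so the width minimum sits exactly at cycle boundaries.
#' When `cfg$coupling` is on, the cycle boundary nearest each supplied
#' C-bend-turn angular-velocity peak is snapped to that peak (below
#' `t_loe - coupling_loss_c` only), programming respiratory-locomotor
#' phase-locking. The trace is quantized to 0.5 mm.
#'
#' @param cfg a `sim_config`.
#' @param t,temp time (s) and temperature (degC) grids, typically from
#'   [simulate_experiment()].
#' @param t_loe loss-of-equilibrium temperature of this run.
#' @param turn_peaks times (s) of C-bend angular-velocity peaks to lock to.
#' @return list with `trace` (an `opercular_trace`), `cycles` (per-cycle
#'   truth: start, full-open and end times, true OA/OT/f_V, temperature,
#'   locked flag) and `curves` (the true parameter functions of temperature).
#' @export
simulate_opercular <- function(cfg, t, temp, t_loe, turn_peaks = numeric(0)) {
  curves <- .ventilation_curves(cfg, t_loe)
  temp_of <- stats::approxfun(t, temp, rule = 2)
  t_end <- t[length(t)]
  cut_t <- t_loe - cfg$coupling_loss_c
  turn_peaks <- sort(turn_peaks)
  # schedule cycle boundaries
  starts <- numeric(0); periods <- numeric(0); locked <- logical(0)
  cur <- t[1]
  tp_i <- 1
  est_n <- ceiling((t_end - t[1]) / (60 / (cfg$fv_base * cfg$fv_fold))) + 10
  starts <- numeric(est_n); periods <- numeric(est_n); locked <- logical(est_n)
  m <- 0
  while (cur < t_end) {
    Tm <- temp_of(cur)
    p <- 60 / curves$fv(Tm)
    if (cfg$fv_jitter_cv > 0) p <- p * max(stats::rnorm(1, 1, cfg$fv_jitter_cv), 0.5)
    lock <- FALSE
    while (tp_i <= length(turn_peaks) && turn_peaks[tp_i] <= cur + 0.25 * p)
      tp_i <- tp_i + 1
    if (isTRUE(cfg$coupling) && tp_i <= length(turn_peaks) && Tm < cut_t) {
      tp <- turn_peaks[tp_i]
      if (tp > cur + 0.25 * p && tp < cur + 1.75 * p) {
        p <- tp - cur
        lock <- TRUE
        tp_i <- tp_i + 1
      }
    }
    m <- m + 1
    starts[m] <- cur; periods[m] <- p; locked[m] <- lock
    cur <- cur + p
  }
  starts <- starts[seq_len(m)]; periods <- periods[seq_len(m)]; locked <- locked[seq_len(m)]
  ctemp <- temp_of(starts)
  oa <- curves$oa(ctemp)
  ot <- pmin(curves$ot(ctemp), 0.6 * periods)

  # sample the trace
  ci <- findInterval(t, starts, rightmost.closed = FALSE)
  ci[ci < 1] <- 1
  s <- t - starts[ci]
  opening <- s <= ot[ci]
  w_base <- cfg$body_width * 10 * 0.85
  w <- ifelse(opening,
              w_base + oa[ci] * 0.5 * (1 - cos(pi * s / ot[ci])),
              w_base + oa[ci] * 0.5 *
                (1 + cos(pi * pmin((s - ot[ci]) / pmax(periods[ci] - ot[ci], 1e-6), 1))))
  if (cfg$op_noise_sd_mm > 0) w <- w + stats::rnorm(length(w), 0, cfg$op_noise_sd_mm)
  w <- round(w / 0.5) * 0.5

  cycles <- data.frame(
    t_start = starts, t_full_open = starts + ot, t_end = starts + periods,
    period_s = periods, fv_true = 60 / periods, oa_true = oa, ot_true = ot,
    temp = ctemp, locked = locked
  )
  list(trace = opercular_trace(t, w, temp, frame_rate = cfg$frame_rate),
       cycles = cycles, curves = curves)
}

#' Simulate a ventilation-only run
#'
#' Draws T_LOE and synthesizes just the temperature log and opercular trace
#' (no trajectory), for ventilation-recovery studies where the locomotor
#' channel is not needed.
#'
#' @param cfg a `sim_config`.
#' @return list with `trace`, `cycles`, `curves`, `t_loe`, `t0`,
#'   `baseline_window`.
#' @export
simulate_ventilation_run <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  t_loe <- .draw_t_loe(cfg)
  ramp_dur <- (t_loe - cfg$t0) / cfg$ramp_rate * 3600
  t <- seq(-cfg$baseline_min * 60, ramp_dur, by = 1 / cfg$frame_rate)
  temp <- pmin(cfg$t0 + cfg$ramp_rate / 3600 * pmax(t, 0), t_loe)
  op <- simulate_opercular(cfg, t, temp, t_loe = t_loe)
  c(op, list(t_loe = t_loe, t0 = cfg$t0, baseline_window = c(t[1], 0)))
}

#' Write a simulated experiment in the on-disk formats the readers accept
#'
#' Emits `trajectory.csv`, `opercular.csv`, `annotations.csv`, `config.yaml`
#' and `ground_truth.tsv` under `dir`. Single-frame tracker dropouts are
#' injected into the coordinate columns at `cfg$dropout_rate` (the readers
#' interpolate them back).
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory.
#' @param cfg the `sim_config` used (for the dropout rate and metadata).
#' @return invisibly, the config path.
#' @export
write_simulated_experiment <- function(sim, dir, cfg) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- sim$experiment; tr <- ex$trajectory
  df <- data.frame(t_s = tr$t, temp_C = tr$temp,
                   x_com_cm = tr$com_x, y_com_cm = tr$com_y,
                   x_snout_cm = tr$snout_x, y_snout_cm = tr$snout_y)
  if (cfg$dropout_rate > 0) {
    nd <- stats::rbinom(1, nrow(df) - 2, cfg$dropout_rate)
    if (nd > 0) {
      i <- sample(2:(nrow(df) - 1), nd)
      df[i, c("x_com_cm", "y_com_cm", "x_snout_cm", "y_snout_cm")] <- NA
    }
  }
  utils::write.csv(df, file.path(dir, "trajectory.csv"), row.names = FALSE)
  if (!is.null(ex$opercular)) {
    utils::write.csv(data.frame(t_s = ex$opercular$t,
                                head_width_mm = ex$opercular$head_width),
                     file.path(dir, "opercular.csv"), row.names = FALSE)
  }
  ann <- ex$annotations
  utils::write.csv(data.frame(kind = ann$kind, t_start_s = ann$t_start,
                              t_end_s = ann$t_end, n_beats = ann$n_beats),
                   file.path(dir, "annotations.csv"), row.names = FALSE)
  conf <- list(
    trajectory_csv = "trajectory.csv",
    annotations_csv = "annotations.csv",
    species = ex$specimen$species,
    body_length_cm = ex$specimen$body_length,
    body_width_cm = ex$specimen$body_width,
    tank_w_cm = ex$tank$width, tank_l_cm = ex$tank$length,
    t0_c = ex$t0, t_loe_c = ex$t_loe,
    baseline_window_s = as.numeric(ex$baseline_window),
    seed = cfg$seed
  )
  if (!is.null(ex$opercular)) conf$opercular_csv <- "opercular.csv"
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(conf, cfg_path)
  utils::write.table(sim$truth$events, file.path(dir, "ground_truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cfg_path)
}
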