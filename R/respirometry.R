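#' Ventilation, fin-behavior and respiratory-locomotor coupling metrics
#'
#' Extracts opercular movement cycles from a head-width trace and derives the
#' ventilation metrics: f_V (cycles per minute), opercula opening amplitude
#' OA (mm, a proxy of ventilatory stroke volume), opening time OT (s, an
#' inverse proxy of branchial-pump suction) and opening velocity OV = OA/OT
#' (a proxy of ventilation efficacy); summarizes fin fanning, splay and
#' surfacing annotations; and quantifies the phase relation between C-bend
#' turns and opercular movements.
#'
#' @name respirometry
NULL

#' Extract opercular cycles from a head-width trace
#'
#' Cycles are segmented at local minima of the smoothed width with
#' prominence at least `cycle_prominence_mm` (0.5 mm, the measurement
#' accuracy of the width readout). Within each cycle, OA is the raw
#' max-minus-min width, the full-open time is the first frame attaining
#' `open_fraction` (95%) of the cycle maximum, OT is that time minus the
#' cycle start (integer frames over the frame rate), and OV = OA/OT.
#' Cycles overlapping fast maneuvers (|Va| above `mask_va`) are dropped when
#' a kinematic series is supplied — width measurements are unreliable during
#' fast motion.
#'
#' @param trace an `opercular_trace`.
#' @param cfg analysis config.
#' @param kin optional `kinematic_series` for high-|Va| masking.
#' @return data.frame of cycles: `t_open_start`, `t_full_open`, `t_close`,
#'   `oa_mm`, `ot_s`, `ov_mm_s`, `temp`. Empty (with a warning) when the
#'   trace spans less than one cycle.
#' @export
extract_cycles <- function(trace, cfg = default_config(), kin = NULL) {
  empty <- data.frame(t_open_start = numeric(0), t_full_open = numeric(0),
                      t_close = numeric(0), oa_mm = numeric(0),
                      ot_s = numeric(0), ov_mm_s = numeric(0), temp = numeric(0))
  w <- trace$head_width
  if (length(w) < 5 || diff(range(w)) < cfg$cycle_prominence_mm) {
    warning("trace spans less than one opercular cycle")
    return(empty)
  }
  ws <- smooth_series(w, cfg$cycle_smooth_window)
  mins <- .find_minima(ws, cfg$cycle_prominence_mm)
  if (length(mins) < 2) {
    warning("trace spans less than one opercular cycle")
    return(empty)
  }
  fr <- trace$frame_rate
  n_cyc <- length(mins) - 1
  i0 <- mins[-length(mins)]
  i1 <- mins[-1]
  oa <- numeric(n_cyc); ot <- numeric(n_cyc); tfo <- numeric(n_cyc)
  t_start <- numeric(n_cyc)
  for (k in seq_len(n_cyc)) {
    idx <- i0[k]:i1[k]
    wk <- w[idx]
    lo <- min(wk); hi <- max(wk)
    oa[k] <- hi - lo
    # opening runs from the last fully-closed frame (end of the raw minimum
    # plateau) to the first frame attaining the open fraction of the maximum
    j_hi <- which(wk >= lo + cfg$open_fraction * (hi - lo))[1]
    closed <- which(wk[seq_len(j_hi)] <= lo + 1e-9)
    j_lo <- if (length(closed)) closed[length(closed)] else 1L
    t_start[k] <- trace$t[idx[j_lo]]
    tfo[k] <- trace$t[idx[j_hi]]
    ot[k] <- max(j_hi - j_lo, 1) / fr
  }
  out <- data.frame(
    t_open_start = t_start, t_full_open = tfo, t_close = trace$t[i1],
    oa_mm = oa, ot_s = ot, ov_mm_s = oa / ot, temp = trace$temp[i0]
  )
  out <- out[out$oa_mm > 0, , drop = FALSE]
  if (!is.null(kin) && nrow(out)) {
    fast <- abs(kin$v_ang) > cfg$mask_va
    if (any(fast)) {
      ft <- kin$t[fast]
      bad <- vapply(seq_len(nrow(out)), function(k)
        any(ft >= out$t_open_start[k] & ft <= out$t_close[k]), logical(1))
      out <- out[!bad, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

# local minima of the (smoothed) width with the given prominence; plateaus
# from the 0.5 mm quantization contribute their central sample
.find_minima <- function(x, prominence) {
  sort(.find_prominent_minima(x, prominence))
}

#' Per-minute ventilation series
#'
#' Consecutive, non-overlapping windows (default 60 s) from the start of the
#' trace: f_V is the count of cycle starts in the window; OA, OT, OV and
#' temperature are window means. Windows without cycles get f_V = 0 and NA
#' metric means.
#'
#' @param cycles data.frame from [extract_cycles()].
#' @param trace the source `opercular_trace` (defines the time span and
#'   temperature of empty windows).
#' @param window_s window length, seconds.
#' @return data.frame: `t_mid`, `temp`, `fv`, `oa_mm`, `ot_s`, `ov_mm_s`.
#' @export
ventilation_series <- function(cycles, trace, window_s = 60) {
  t0 <- trace$t[1]; t1 <- trace$t[length(trace$t)]
  edges <- seq(t0, t1, by = window_s)
  if (length(edges) < 2) stop("trace shorter than one window")
  nw <- length(edges) - 1
  idx <- findInterval(cycles$t_open_start, edges, rightmost.closed = FALSE)
  idx[idx < 1 | idx > nw] <- NA
  out <- data.frame(
    t_mid = edges[-length(edges)] + window_s / 2,
    temp = stats::approx(trace$t, trace$temp,
                         xout = edges[-length(edges)] + window_s / 2, rule = 2)$y,
    fv = tabulate(idx[!is.na(idx)], nbins = nw),
    oa_mm = NA_real_, ot_s = NA_real_, ov_mm_s = NA_real_
  )
  for (k in unique(idx[!is.na(idx)])) {
    g <- cycles[which(idx == k), ]
    out$oa_mm[k] <- mean(g$oa_mm)
    out$ot_s[k] <- mean(g$ot_s)
    out$ov_mm_s[k] <- mean(g$ov_mm_s)
  }
  # window-scaled to cycles per minute
  out$fv <- out$fv * 60 / window_s
  out
}

#' Normalize a ventilation series to its baseline value
#'
#' Divides each metric by its mean over the baseline window, so the baseline
#' maps to 1 (per-animal normalization, applied before cross-specimen
#' averaging). Normalizing an already-normalized series is the identity.
#'
#' @param series data.frame from [ventilation_series()].
#' @param baseline_window numeric length-2, seconds; windows whose midpoint
#'   falls inside are the baseline (at least one required).
#' @param cols metric columns to normalize.
#' @return `series` with the columns replaced by normalized values.
#' @export
normalize_to_initial <- function(series, baseline_window,
                                 cols = c("fv", "oa_mm", "ot_s", "ov_mm_s")) {
  base <- series$t_mid >= baseline_window[1] & series$t_mid <= baseline_window[2]
  if (!any(base)) stop("baseline window contains no records")
  for (cl in cols) {
    b <- mean(series[[cl]][base], na.rm = TRUE)
    if (!is.finite(b) || b == 0) stop("baseline mean undefined for ", cl)
    series[[cl]] <- series[[cl]] / b
  }
  series
}

#' Fin-behavior metrics from annotation events
#'
#' Fanning-bout durations and frequencies (beats per second within a bout),
#' splay durations, and surfacing counts/durations, each carried with its
#' event temperature.
#'
#' @param fins a `fin_events` data.frame.
#' @return list of data.frames: `fanning` (`temp`, `dur_s`, `freq_hz`),
#'   `splay` (`temp`, `dur_s`), `surfacing` (`temp`, `dur_s`), and `counts`.
#' @export
fin_metrics <- function(fins) {
  dur <- fins$t_end - fins$t_start
  fan <- fins$kind == "FANNING_BOUT"
  spl <- fins$kind == "SPLAY"
  srf <- fins$kind == "SURFACING"
  list(
    fanning = data.frame(temp = fins$temp[fan], dur_s = dur[fan],
                         freq_hz = fins$n_beats[fan] / dur[fan]),
    splay = data.frame(temp = fins$temp[spl], dur_s = dur[spl]),
    surfacing = data.frame(temp = fins$temp[srf], dur_s = dur[srf]),
    counts = data.frame(kind = c("FANNING_BOUT", "SPLAY", "SURFACING"),
                        n = c(sum(fan), sum(spl), sum(srf)))
  )
}

#' Pearson correlation of two ventilation series on a common %T_LOE grid
#'
#' Both series are interpolated onto a shared normalized-thermal-range grid
#' over their overlap; the correlation is computed across grid points.
#'
#' @param series_a,series_b data.frames with a metric column and a `pct`
#'   column (%T_LOE of each record).
#' @param col metric column name (default `"fv"`).
#' @param grid_step grid spacing in %T_LOE (default 1).
#' @return Pearson r.
#' @export
ventilation_correlation <- function(series_a, series_b, col = "fv", grid_step = 1) {
  ok_a <- is.finite(series_a$pct) & is.finite(series_a[[col]])
  ok_b <- is.finite(series_b$pct) & is.finite(series_b[[col]])
  lo <- max(min(series_a$pct[ok_a]), min(series_b$pct[ok_b]))
  hi <- min(max(series_a$pct[ok_a]), max(series_b$pct[ok_b]))
  if (hi <= lo) stop("series do not overlap on the %T_LOE axis")
  grid <- seq(lo, hi, by = grid_step)
  a <- stats::approx(series_a$pct[ok_a], series_a[[col]][ok_a], xout = grid,
                     ties = mean)$y
  b <- stats::approx(series_b$pct[ok_b], series_b[[col]][ok_b], xout = grid,
                     ties = mean)$y
  stats::cor(a, b, use = "complete.obs")
}

#' Respiratory-locomotor coupling profiles
#'
#' For every single-stage C-bend turn, |Va| and head width are extracted over
#' a window around turn onset (default -0.5 to +1.5 s), normalized per turn
#' (|Va| by its window maximum; width to [0, 1] over its window range, 1 =
#' opercula open), and averaged within 1 degC temperature bins. The scalar
#' synchrony statistic per turn is the lag of the opercular minimum nearest
#' the |Va| peak, located on the smoothed width with sub-plateau centering;
#' per bin the mean lag is reported. Under phase-locking the opercular
#' minimum coincides with the |Va| peak (lag ~ 0, closure at maximal head
#' rotation); without coupling the nearest-minimum lag is uniform over one
#' cycle.
#'
#' @param events classified maneuver events.
#' @param trace an `opercular_trace`.
#' @param kin the `kinematic_series`.
#' @param cfg analysis config (`coupling_window_s`, `coupling_bin_c`,
#'   `cycle_smooth_window`).
#' @return list with `profiles` (per-bin mean/SD normalized |Va| and width on
#'   the relative time grid), `turns` (per-turn lag table: `temp`, `lag_s`,
#'   `lag_frames`, `period_s`), and `bins` (per-bin `n_turns`, `mean_lag_s`,
#'   `mean_lag_frames`).
#' @export
coupling_profile <- function(events, trace, kin, cfg = default_config()) {
  turns <- events[events$klass == "C_BEND_SINGLE", , drop = FALSE]
  fr <- trace$frame_rate
  w0 <- cfg$coupling_window_s[1]; w1 <- cfg$coupling_window_s[2]
  grid_fr <- seq(round(w0 * fr), round(w1 * fr))
  grid <- grid_fr / fr
  ng <- length(grid)
  ws <- smooth_series(trace$head_width, cfg$cycle_smooth_window)
  absva <- abs(kin$v_ang)
  # both series are uniformly sampled; index arithmetic replaces interpolation
  kin_i <- function(tt) round((tt - kin$t[1]) * fr) + 1
  tr_i <- function(tt) round((tt - trace$t[1]) * trace$frame_rate) + 1
  nk <- length(kin$t); nt <- length(trace$t)
  va_mat <- matrix(NA_real_, nrow(turns), ng)
  hw_mat <- matrix(NA_real_, nrow(turns), ng)
  lag_s <- rep(NA_real_, nrow(turns)); period <- rep(NA_real_, nrow(turns))
  # minima search spans at least one expected cycle either side of the peak
  half_span <- max(w1 - w0, 2.5)
  for (i in seq_len(nrow(turns))) {
    ik <- kin_i(turns$t_onset[i]) + grid_fr
    it <- tr_i(turns$t_onset[i]) + grid_fr
    if (ik[1] < 1 || ik[ng] > nk || it[1] < 1 || it[ng] > nt) next
    va_i <- absva[ik]
    hw_i <- ws[it]
    va_mat[i, ] <- va_i / max(va_i)
    rng <- range(hw_i)
    hw_mat[i, ] <- if (diff(rng) > 0) (hw_i - rng[1]) / diff(rng) else 0.5
    # locate opercular minima around the Va peak; the nearest one is the lag
    t_pk <- turns$t_peak[i]
    is <- tr_i(t_pk - half_span):tr_i(t_pk + half_span)
    is <- is[is >= 1 & is <= nt]
    if (length(is) < 5) next
    prom <- max(0.25, 0.2 * diff(range(ws[is])))
    mins_rel <- .window_minima_prom(ws[is], (is - tr_i(t_pk)) / trace$frame_rate, prom)
    t_mins <- t_pk + mins_rel
    # require minima bracketing the peak so the nearest lies within half a
    # cycle; otherwise the lag is undefined
    if (!any(t_mins <= t_pk) || !any(t_mins >= t_pk)) next
    k <- which.min(abs(t_mins - t_pk))
    lag_s[i] <- t_mins[k] - t_pk
    if (length(t_mins) >= 2) period[i] <- stats::median(diff(t_mins))
  }
  turns$lag_s <- lag_s
  turns$lag_frames <- lag_s * fr
  turns$period_s <- period
  ok <- !is.na(lag_s)
  bins_out <- data.frame(temp_lo = numeric(0), n_turns = integer(0),
                         mean_lag_s = numeric(0), mean_lag_frames = numeric(0))
  profiles <- list()
  if (any(ok)) {
    df <- data.frame(temp = turns$temp_onset, idx = seq_len(nrow(turns)))[ok, ]
    groups <- bin_by_temperature(df, cfg$coupling_bin_c)
    for (nm in names(groups)) {
      ii <- groups[[nm]]$idx
      profiles[[nm]] <- data.frame(
        rel_t = grid,
        va_mean = colMeans(va_mat[ii, , drop = FALSE]),
        va_sd = apply(va_mat[ii, , drop = FALSE], 2, stats::sd),
        hw_mean = colMeans(hw_mat[ii, , drop = FALSE]),
        hw_sd = apply(hw_mat[ii, , drop = FALSE], 2, stats::sd)
      )
      bins_out <- rbind(bins_out, data.frame(
        temp_lo = as.numeric(nm), n_turns = length(ii),
        mean_lag_s = mean(turns$lag_s[ii]),
        mean_lag_frames = mean(turns$lag_frames[ii])
      ))
    }
  }
  list(profiles = profiles, turns = turns[, c("t_onset", "t_peak", "temp_onset",
                                              "lag_s", "lag_frames", "period_s")],
       bins = bins_out)
}

# prominence-filtered local minima of a windowed series, as times on the
# supplied relative grid (plateaus contribute their central sample)
.window_minima_prom <- function(x, rel_t, prominence) {
  rel_t[.find_prominent_minima(x, prominence)]
}
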