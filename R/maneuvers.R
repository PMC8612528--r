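#' Startle-like maneuver detection, classification and lateralization
#'
#' Detects supra-threshold angular-velocity events in a kinematic series,
#' classifies them into the four thermally induced startle-like classes
#' (fast S-bend, single-stage C-bend, multi-stage C-bend, withdrawal-like
#' retraction), applies near-wall exclusion, tallies turns per temperature
#' increment, computes relative lateralization (LR) profiles across the
#' normalized thermal range with their one-sample tests, and detects
#' Splay-Turn-Glide fixed-action-pattern triplets.
#'
#' @name maneuvers
NULL

# close short FALSE-gaps in a logical run (hysteresis dropouts)
.close_gaps <- function(mask, max_gap) {
  r <- rle(mask)
  short <- !r$values & r$lengths < max_gap
  # never bridge the boundaries
  short[c(1, length(short))] <- FALSE
  r$values[short] <- TRUE
  inverse.rle(r)
}

#' Detect candidate turning maneuvers
#'
#' Events are runs where |Va| exceeds the onset threshold for at least
#' `turn_min_frames`, extended by hysteresis down to the offset threshold
#' (dips below it shorter than `turn_offset_frames` do not close an event),
#' and merged when closer than `turn_merge_gap_s`. Each event carries the
#' features the classifier uses: peak |Va| (and its sign), the number of
#' prominence-filtered |Va| peaks, and the net center-of-mass displacement
#' along the pre-turn heading in body lengths (negative = backward).
#'
#' @param kin a `kinematic_series` (see [kinematic_series()]).
#' @param traj the source `trajectory` (for displacement features).
#' @param specimen the `specimen` (body length).
#' @param cfg analysis config (see [default_config()]).
#' @return data.frame of events: `t_onset`, `t_offset`, `t_peak`,
#'   `temp_onset`, `peak_va` (signed Va at peak), `peak_va_abs`,
#'   `n_va_peaks`, `net_disp_bl`, `com_x`, `com_y`. Empty when nothing
#'   exceeds threshold.
#' @export
detect_turns <- function(kin, traj, specimen, cfg = default_config()) {
  absva <- abs(kin$v_ang)
  fr <- attr(kin, "frame_rate") %||% traj$frame_rate
  empty <- data.frame(t_onset = numeric(0), t_offset = numeric(0),
                      t_peak = numeric(0), temp_onset = numeric(0),
                      peak_va = numeric(0), peak_va_abs = numeric(0),
                      n_va_peaks = integer(0), net_disp_bl = numeric(0),
                      com_x = numeric(0), com_y = numeric(0))
  active <- absva >= cfg$turn_offset_va
  if (!any(active)) return(empty)
  active <- .close_gaps(active, cfg$turn_offset_frames)
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  # a segment is an event only if it contains a core of >= turn_min_frames
  # consecutive frames at or above the onset threshold
  has_core <- vapply(seq_len(nrow(seg)), function(i) {
    rr <- rle(absva[seg$start[i]:seg$end[i]] >= cfg$turn_onset_va)
    any(rr$values & rr$lengths >= cfg$turn_min_frames)
  }, logical(1))
  seg <- seg[has_core, , drop = FALSE]
  if (!nrow(seg)) return(empty)
  # merge events separated by less than the merge gap
  merge_frames <- round(cfg$turn_merge_gap_s * fr)
  if (nrow(seg) > 1) {
    keep_start <- seg$start[1]; out <- NULL
    cur_end <- seg$end[1]
    for (i in seq_len(nrow(seg))[-1]) {
      if (seg$start[i] - cur_end < merge_frames) {
        cur_end <- seg$end[i]
      } else {
        out <- rbind(out, c(keep_start, cur_end))
        keep_start <- seg$start[i]; cur_end <- seg$end[i]
      }
    }
    out <- rbind(out, c(keep_start, cur_end))
    seg <- data.frame(start = out[, 1], end = out[, 2])
  }

  bl <- specimen$body_length
  n <- nrow(seg)
  res <- empty[rep(1, n), ]
  for (i in seq_len(n)) {
    idx <- seg$start[i]:seg$end[i]
    # duration-adaptive peak estimation: long (slow) events tolerate
    # smoothing that suppresses tracker noise without eroding the true peak,
    # while short S-bend pulses are left raw (any smoothing would clip them)
    w <- min(7L, length(idx) %/% 6L)
    if (w %% 2L == 0L) w <- max(w - 1L, 1L)
    vs <- smooth_series(kin$v_ang[idx], max(w, 1L))
    j_pk <- which.max(abs(vs))
    ipk <- idx[j_pk]
    # pre-turn heading a few frames before onset
    i_pre <- max(seg$start[i] - 3, 1)
    h0 <- kin$heading[i_pre] * pi / 180
    dx <- traj$com_x[seg$end[i]] - traj$com_x[seg$start[i]]
    dy <- traj$com_y[seg$end[i]] - traj$com_y[seg$start[i]]
    pk <- if (length(idx) >= 3)
      .count_prominent_peaks(abs(vs), cfg$peak_prominence_va) else 1L
    res$t_onset[i] <- kin$t[seg$start[i]]
    res$t_offset[i] <- kin$t[seg$end[i]]
    res$t_peak[i] <- kin$t[ipk]
    res$temp_onset[i] <- kin$temp[seg$start[i]]
    res$peak_va[i] <- vs[j_pk]
    res$peak_va_abs[i] <- abs(vs[j_pk])
    res$n_va_peaks[i] <- pk
    res$net_disp_bl[i] <- (dx * cos(h0) + dy * sin(h0)) / bl
    res$com_x[i] <- traj$com_x[seg$start[i]]
    res$com_y[i] <- traj$com_y[seg$start[i]]
  }
  rownames(res) <- NULL
  res
}

#' Classify detected maneuvers
#'
#' Decision rule, anchored at the observed angular-velocity bands:
#' \itemize{
#'   \item WITHDRAWAL: peak |Va| < `withdrawal_va` (50 deg/s) and net
#'     backward displacement > `withdrawal_disp_bl` (0.05 BL); direction NONE.
#'   \item S_BEND: peak |Va| > `sbend_va` (500 deg/s).
#'   \item C_BEND_MULTI: peak |Va| < `cmulti_va` (100 deg/s) with >= 2
#'     prominence-filtered Va peaks.
#'   \item C_BEND_SINGLE: everything else; events in the unassigned band
#'     (100, 500] deg/s with multiple peaks keep a `band_ambiguous` flag.
#' }
#' Direction is the sign of Va at the peak (positive = RIGHT).
#'
#' @param events data.frame from [detect_turns()].
#' @param cfg analysis config.
#' @return `events` with `klass`, `direction`, `band_ambiguous` columns.
#' @export
classify_maneuver <- function(events, cfg = default_config()) {
  n <- nrow(events)
  klass <- character(n); flag <- logical(n)
  back <- pmax(-events$net_disp_bl, 0)
  for (i in seq_len(n)) {
    pk <- events$peak_va_abs[i]
    if (pk < cfg$withdrawal_va && back[i] > cfg$withdrawal_disp_bl) {
      klass[i] <- "WITHDRAWAL"
    } else if (pk > cfg$sbend_va) {
      klass[i] <- "S_BEND"
    } else if (pk < cfg$cmulti_va && events$n_va_peaks[i] >= 2) {
      klass[i] <- "C_BEND_MULTI"
    } else {
      klass[i] <- "C_BEND_SINGLE"
      flag[i] <- pk > cfg$cmulti_va && events$n_va_peaks[i] >= 2
    }
  }
  events$klass <- klass
  events$direction <- ifelse(klass == "WITHDRAWAL", "NONE",
                             ifelse(events$peak_va > 0, "RIGHT", "LEFT"))
  events$band_ambiguous <- flag
  events
}

#' Near-wall flag for turn exclusion
#'
#' A turn is near-wall when the center of mass at onset lies strictly closer
#' to the nearest wall than `cutoff_bl` body lengths (default one half).
#' A distance exactly at the cutoff counts as free.
#'
#' @param events events with `com_x`, `com_y` (onset position).
#' @param tank a `tank_geometry`.
#' @param specimen the `specimen`.
#' @param cutoff_bl cutoff in body lengths (default 0.5).
#' @return logical vector (TRUE = near wall, excluded from laterality).
#' @export
flag_near_wall <- function(events, tank, specimen, cutoff_bl = 0.5) {
  wall_distance(tank, events$com_x, events$com_y) < cutoff_bl * specimen$body_length
}

#' Tally C-bend turns per absolute-temperature increment
#'
#' Counts free (non-near-wall) C-bend turns in half-open `width`-degC bins
#' (default 0.5). Near-wall C-bends are reported as `excluded`; the bin
#' counts plus the excluded count always equal the total C-bend count.
#'
#' @param events classified events (with `klass`, `direction`, `near_wall`,
#'   `temp_onset`).
#' @param width bin width, degC.
#' @return list with `bins` (data.frame: `temp_lo`, `n`, `n_right`,
#'   `n_left`), `excluded`, `total_cbend`.
#' @export
tally_turns <- function(events, width = 0.5) {
  cb <- events[events$klass %in% c("C_BEND_SINGLE", "C_BEND_MULTI"), , drop = FALSE]
  free <- cb[!cb$near_wall, , drop = FALSE]
  if (nrow(free)) {
    free$temp <- free$temp_onset
    groups <- bin_by_temperature(free, width)
    bins <- data.frame(
      temp_lo = as.numeric(names(groups)),
      n = vapply(groups, nrow, integer(1)),
      n_right = vapply(groups, function(g) sum(g$direction == "RIGHT"), integer(1)),
      n_left = vapply(groups, function(g) sum(g$direction == "LEFT"), integer(1))
    )
    rownames(bins) <- NULL
  } else {
    bins <- data.frame(temp_lo = numeric(0), n = integer(0),
                       n_right = integer(0), n_left = integer(0))
  }
  list(bins = bins, excluded = nrow(cb) - nrow(free), total_cbend = nrow(cb))
}

#' Relative lateralization index
#'
#' `LR = 100 * (n_right - n_left) / (n_right + n_left)`, in percent:
#' 100 when the fish turned right in every tallied maneuver, -100 when it
#' always turned left, near 0 when unbiased. Undefined (NA) when there are
#' no tallied turns — an empty bin carries no laterality information and is
#' not 0.
#'
#' @param n_right,n_left turn counts.
#' @return LR in [-100, 100], or NA when both counts are zero.
#' @export
lateralization_index <- function(n_right, n_left) {
  tot <- n_right + n_left
  ifelse(tot > 0, 100 * (n_right - n_left) / tot, NA_real_)
}

# per-specimen LR in 5 %T_LOE bins from classified events
.specimen_lr_bins <- function(events, bin_pct = 5) {
  edges <- seq(0, 100, by = bin_pct)
  nb <- length(edges) - 1
  cb <- events[events$klass %in% c("C_BEND_SINGLE", "C_BEND_MULTI") &
                 !events$near_wall & events$direction != "NONE", , drop = FALSE]
  idx <- findInterval(cb$pct_tloe, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > nb] <- NA
  n_right <- tabulate(idx[cb$direction == "RIGHT" & !is.na(idx)], nbins = nb)
  n_left <- tabulate(idx[cb$direction == "LEFT" & !is.na(idx)], nbins = nb)
  data.frame(bin = seq_len(nb), pct_lo = edges[-length(edges)], pct_hi = edges[-1],
             n_right = n_right, n_left = n_left,
             lr = lateralization_index(n_right, n_left))
}

#' Cohort lateralization profile across the normalized thermal range
#'
#' For each specimen, free C-bend turns are tallied in `bin_pct` %T_LOE
#' increments and converted to LR indices; across specimens each bin gets
#' mean LR, SEM, and a two-tailed one-sample t-test against 0 (random
#' choice). Bins where fewer than two specimens have a defined LR are
#' reported untested; zero-variance bins are tested degenerately (flagged,
#' p at the machine floor when the common LR is nonzero).
#'
#' @param specimen_events list (one element per specimen) of classified event
#'   data.frames that carry `pct_tloe`, `near_wall`, `direction`, `klass`.
#' @param bin_pct bin width in %T_LOE (default 5).
#' @return data.frame with one row per bin: `pct_lo`, `pct_hi`,
#'   `n_specimens`, `mean_lr`, `sem_lr`, `t`, `df`, `p`, `tested`,
#'   `degenerate`, `n_right`, `n_left`.
#' @export
laterality_profile <- function(specimen_events, bin_pct = 5) {
  per <- lapply(specimen_events, .specimen_lr_bins, bin_pct = bin_pct)
  nb <- nrow(per[[1]])
  out <- per[[1]][, c("pct_lo", "pct_hi")]
  out$n_specimens <- 0L; out$mean_lr <- NA_real_; out$sem_lr <- NA_real_
  out$t <- NA_real_; out$df <- NA_real_; out$p <- NA_real_
  out$tested <- FALSE; out$degenerate <- FALSE
  out$n_right <- 0L; out$n_left <- 0L
  for (b in seq_len(nb)) {
    vals <- vapply(per, function(d) d$lr[b], numeric(1))
    out$n_right[b] <- sum(vapply(per, function(d) d$n_right[b], numeric(1)))
    out$n_left[b] <- sum(vapply(per, function(d) d$n_left[b], numeric(1)))
    vals <- vals[!is.na(vals)]
    out$n_specimens[b] <- length(vals)
    if (length(vals)) {
      out$mean_lr[b] <- mean(vals)
      out$sem_lr[b] <- stats::sd(vals) / sqrt(length(vals))
    }
    if (length(vals) >= 2) {
      tt <- one_sample_ttest(vals, 0)
      out$t[b] <- tt$t; out$df[b] <- tt$df; out$p[b] <- tt$p
      out$tested[b] <- TRUE; out$degenerate[b] <- tt$degenerate
    }
  }
  out
}

#' Detect Splay-Turn-Glide triplets
#'
#' Greedy left-to-right matching of the fixed-action-pattern sequence: a fin
#' splay, then a single-stage C-bend turn whose onset falls within
#' `triplet_max_gap_s` of the splay end, then a glide — a post-turn interval
#' of at least `glide_min_s` where the fish is translating (initial v_lin
#' above `glide_min_v_bl_s`), slowing down, and beating no fins. Each
#' sub-event is used at most once; component order is strict.
#'
#' @param man_events classified maneuver events.
#' @param fins a `fin_events` data.frame.
#' @param kin the `kinematic_series` (for the glide check).
#' @param cfg analysis config; uses `triplet_max_gap_s`, `glide_min_s`, plus
#'   `glide_min_v_bl_s` (default 0.08) if present.
#' @return data.frame of triplets: `t_splay_start`, `t_splay_end`, `t_turn`,
#'   `t_glide_start`, `temp`.
#' @export
detect_triplets <- function(man_events, fins, kin, cfg = default_config()) {
  out <- data.frame(t_splay_start = numeric(0), t_splay_end = numeric(0),
                    t_turn = numeric(0), t_glide_start = numeric(0),
                    temp = numeric(0))
  splays <- fins[fins$kind == "SPLAY", , drop = FALSE]
  turns <- man_events[man_events$klass == "C_BEND_SINGLE", , drop = FALSE]
  fan <- fins[fins$kind == "FANNING_BOUT", , drop = FALSE]
  if (!nrow(splays) || !nrow(turns)) return(out)
  splays <- splays[order(splays$t_start), ]
  turns <- turns[order(turns$t_onset), ]
  min_v <- cfg$glide_min_v_bl_s %||% 0.08
  used_turn <- rep(FALSE, nrow(turns))
  for (i in seq_len(nrow(splays))) {
    cand <- which(!used_turn &
                    turns$t_onset > splays$t_end[i] &
                    turns$t_onset <= splays$t_end[i] + cfg$triplet_max_gap_s)
    if (!length(cand)) next
    j <- cand[1]
    g0 <- turns$t_offset[j]
    g1 <- g0 + max(cfg$glide_min_s, 1)
    w <- which(kin$t >= g0 & kin$t <= g1)
    if (length(w) < 6) next
    v <- kin$v_lin[w]
    third <- max(floor(length(v) / 3), 1)
    moving <- mean(v[seq_len(third)]) >= min_v
    slowing <- mean(v[seq_len(third)]) > mean(v[(length(v) - third + 1):length(v)])
    no_beats <- !nrow(fan) || !any(fan$t_start < g1 & fan$t_end > g0)
    if (moving && slowing && no_beats) {
      used_turn[j] <- TRUE
      out <- rbind(out, data.frame(
        t_splay_start = splays$t_start[i], t_splay_end = splays$t_end[i],
        t_turn = turns$t_onset[j], t_glide_start = g0,
        temp = turns$temp_onset[j]))
    }
  }
  out
}

#' Run the full maneuver pipeline on one experiment
#'
#' Kinematics, turn detection, classification, wall flags and %T_LOE
#' coordinates in one call.
#'
#' @param ex a `ramp_experiment`.
#' @param cfg analysis config.
#' @return list with `kin` and classified `events`.
#' @export
maneuver_pipeline <- function(ex, cfg = default_config()) {
  kin <- kinematic_series(ex$trajectory, ex$specimen,
                          smooth_window = cfg$smooth_window,
                          heading_window = cfg$heading_window)
  events <- detect_turns(kin, ex$trajectory, ex$specimen, cfg)
  events <- classify_maneuver(events, cfg)
  events$near_wall <- flag_near_wall(events, ex$tank, ex$specimen, cfg$wall_cutoff_bl)
  events$pct_tloe <- percent_tloe(events$temp_onset, ex$t0, ex$t_loe)
  list(kin = kin, events = events)
}
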