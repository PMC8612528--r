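#' Analyze one ramp experiment end to end
#'
#' Runs the full single-specimen pipeline: kinematics, maneuver detection and
#' classification, wall flags, turn tallies, per-specimen laterality bins,
#' opercular cycle extraction and ventilation series (when a trace is
#' present, normalized to the baseline window), fin metrics, triplet
#' detection, and coupling profiles. The returned bundle is ready for
#' [write_results()].
#'
#' @param ex a `ramp_experiment`.
#' @param cfg analysis config (see [default_config()]).
#' @return named list of result tables (`events`, `tally`,
#'   `laterality_bins`, `ventilation`, `cycles`, `fanning`, `splay`,
#'   `surfacing`, `triplets`, `coupling_bins`, `summary`), plus `kin`.
#' @export
analyze_experiment <- function(ex, cfg = default_config()) {
  mp <- maneuver_pipeline(ex, cfg)
  events <- mp$events
  tal <- tally_turns(events, cfg$tally_bin_c)
  lr_bins <- .specimen_lr_bins(events, cfg$laterality_bin_pct)
  out <- list(kin = mp$kin, events = events, tally = tal$bins,
              laterality_bins = lr_bins)
  summary <- data.frame(
    metric = c("n_events", "n_cbend", "n_cbend_excluded_near_wall",
               "t_loe_c", "t0_c", "elongation_ratio"),
    value = c(nrow(events), tal$total_cbend, tal$excluded,
              ex$t_loe, ex$t0, ex$specimen$elongation_ratio)
  )
  if (!is.null(ex$opercular)) {
    cycles <- extract_cycles(ex$opercular, cfg, kin = mp$kin)
    vent <- ventilation_series(cycles, ex$opercular, cfg$fv_window_s)
    vent$pct <- percent_tloe(vent$temp, ex$t0, ex$t_loe)
    vent_norm <- normalize_to_initial(vent, ex$baseline_window)
    out$cycles <- cycles
    out$ventilation <- vent
    out$ventilation_norm <- vent_norm
    cp <- coupling_profile(events, ex$opercular, mp$kin, cfg)
    out$coupling_bins <- cp$bins
    out$coupling_turns <- cp$turns
  }
  if (nrow(ex$annotations)) {
    fm <- fin_metrics(ex$annotations)
    out$fanning <- fm$fanning
    out$splay <- fm$splay
    out$surfacing <- fm$surfacing
    out$triplets <- detect_triplets(events, ex$annotations, mp$kin, cfg)
  }
  out$summary <- summary
  out
}

#' Species-level comparison of loss-of-equilibrium temperatures
#'
#' Welch two-sample test of per-specimen T_LOE between two groups, reporting
#' the group means with SEM, the Welch-Satterthwaite degrees of freedom, and
#' (for transparency) the pooled df alongside.
#'
#' @param t_loe_a,t_loe_b per-specimen T_LOE values of the two groups, degC.
#' @param alpha significance level for the critical value (default 0.05).
#' @return data.frame with one row of summary statistics.
#' @export
compare_t_loe <- function(t_loe_a, t_loe_b, alpha = 0.05) {
  tt <- welch_ttest(t_loe_a, t_loe_b)
  data.frame(
    mean_a = mean(t_loe_a), sem_a = stats::sd(t_loe_a) / sqrt(length(t_loe_a)),
    mean_b = mean(t_loe_b), sem_b = stats::sd(t_loe_b) / sqrt(length(t_loe_b)),
    t = tt$t, df_welch = tt$df,
    df_pooled = length(t_loe_a) + length(t_loe_b) - 2,
    p = tt$p,
    t_crit = t_critical(alpha, round(tt$df))
  )
}
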