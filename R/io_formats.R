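#' Domain objects and on-disk formats
#'
#' Constructors/validators for the experiment containers, readers for the
#' tracker-export CSV dialect, opercular and annotation CSVs, the YAML run
#' configuration, and the TSV result writer. Coordinate convention: origin at
#' a tank corner, x rightward, y up, in the corrected (de-mirrored) ventral
#' view; all inputs are assumed already de-mirrored.
#'
#' @name io_formats
NULL

# ---- constructors -----------------------------------------------------------

#' Specimen metadata
#'
#' @param species `"HB_PLUS"` (hemoglobin-expressing) or `"HB_MINUS"`
#'   (hemoglobinless icefish).
#' @param body_length,body_width in cm; length must exceed width.
#' @return a `specimen` object (list) with the derived `elongation_ratio`.
#' @export
specimen <- function(species = c("HB_PLUS", "HB_MINUS"), body_length, body_width) {
  species <- match.arg(species)
  if (!(body_length > body_width && body_width > 0))
    stop("require body_length > body_width > 0")
  structure(
    list(species = species, body_length = body_length, body_width = body_width,
         elongation_ratio = body_length / body_width),
    class = "specimen"
  )
}

#' Tank geometry
#'
#' @param width,length interior dimensions in cm (default 93 x 93).
#' @return a `tank_geometry` object.
#' @export
tank_geometry <- function(width = 93, length = 93) {
  if (width <= 0 || length <= 0) stop("tank dimensions must be positive")
  structure(list(width = width, length = length), class = "tank_geometry")
}

#' Distance from interior points to the nearest tank wall
#'
#' @param tank a `tank_geometry`.
#' @param x,y coordinates in cm (origin at a corner).
#' @return distances in cm (negative values would indicate points outside).
#' @export
wall_distance <- function(tank, x, y) {
  pmin(x, tank$width - x, y, tank$length - y)
}

#' Trajectory container
#'
#' Per-frame time, temperature and center-of-mass / snout coordinates for one
#' specimen. Validates array lengths, uniform 30 Hz (or given) sampling,
#' finiteness, and that the temperature is non-decreasing during the ramp
#' (t >= 0) up to a 0.2 degC jitter tolerance.
#'
#' @param t time in seconds (strictly increasing, uniform spacing).
#' @param temp water temperature, degC.
#' @param com_x,com_y center-of-mass coordinates, cm.
#' @param snout_x,snout_y snout coordinates, cm (optional: `NULL` when only
#'   linear metrics are needed).
#' @param frame_rate sampling rate, Hz (default 30).
#' @param time_jitter_tol_s tolerated deviation of frame spacing from
#'   1/frame_rate, seconds.
#' @param tank optional `tank_geometry`; when given, coordinates must lie
#'   inside it.
#' @return a `trajectory` object.
#' @export
trajectory <- function(t, temp, com_x, com_y, snout_x = NULL, snout_y = NULL,
                       frame_rate = 30, time_jitter_tol_s = 2e-4, tank = NULL) {
  n <- length(t)
  lens <- c(length(temp), length(com_x), length(com_y))
  if (!is.null(snout_x)) lens <- c(lens, length(snout_x), length(snout_y))
  if (any(lens != n)) stop("all trajectory channels must have equal length")
  if (n >= 2) {
    dt <- diff(t)
    if (any(dt <= 0)) stop("time must be strictly increasing")
    if (any(abs(dt - 1 / frame_rate) > time_jitter_tol_s))
      stop("non-uniform timestamps beyond tolerance (expected spacing ",
           signif(1 / frame_rate, 6), " s)")
  }
  for (nm in c("temp", "com_x", "com_y", "snout_x", "snout_y")) {
    v <- get(nm)
    if (!is.null(v) && any(!is.finite(v))) stop("non-finite values in ", nm)
  }
  ramp <- which(t >= 0)
  if (length(ramp) > 1) {
    dtemp <- diff(temp[ramp])
    if (any(dtemp < -0.2))
      stop("temperature decreases by more than the 0.2 degC jitter tolerance during the ramp")
  }
  if (!is.null(tank)) {
    if (any(com_x < 0 | com_x > tank$width | com_y < 0 | com_y > tank$length))
      stop("center-of-mass coordinates outside tank bounds")
  }
  structure(
    list(t = t, temp = temp, com_x = com_x, com_y = com_y,
         snout_x = snout_x, snout_y = snout_y, frame_rate = frame_rate),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames at %g Hz, t in [%.2f, %.2f] s, temp in [%.2f, %.2f] degC\n",
              length(x$t), x$frame_rate, min(x$t), max(x$t), min(x$temp), max(x$temp)))
  invisible(x)
}

#' Opercular head-width trace
#'
#' @param t seconds; `head_width` in mm (expected quantized to 0.5 mm);
#'   `temp` degC.
#' @param frame_rate Hz.
#' @return an `opercular_trace` object.
#' @export
opercular_trace <- function(t, head_width, temp, frame_rate = 30) {
  if (length(t) != length(head_width) || length(t) != length(temp))
    stop("t, head_width and temp must have equal length")
  if (any(head_width <= 0)) stop("head widths must be positive")
  structure(list(t = t, head_width = head_width, temp = temp, frame_rate = frame_rate),
            class = "opercular_trace")
}

#' Fin/surface annotation events
#'
#' @param kind one of `"FANNING_BOUT"`, `"SPLAY"`, `"SURFACING"` per row.
#' @param t_start,t_end seconds; `t_end > t_start`.
#' @param n_beats fin-beat counts (fanning bouts only; `NA` otherwise).
#' @param temp event temperature, degC (optional; can be filled from a
#'   trajectory later).
#' @return a `fin_events` data.frame.
#' @export
fin_events <- function(kind = character(0), t_start = numeric(0),
                       t_end = numeric(0), n_beats = NA_real_, temp = NA_real_) {
  kinds <- c("FANNING_BOUT", "SPLAY", "SURFACING")
  if (!all(kind %in% kinds)) stop("unknown fin-event kind")
  df <- data.frame(kind = kind, t_start = t_start, t_end = t_end,
                   n_beats = rep_len(n_beats, length(kind)),
                   temp = rep_len(temp, length(kind)))
  if (any(df$t_end <= df$t_start)) stop("fin events must have t_end > t_start")
  fan <- df$kind == "FANNING_BOUT"
  if (any(fan & (is.na(df$n_beats) | df$n_beats < 1)))
    stop("fanning bouts require n_beats >= 1")
  class(df) <- c("fin_events", "data.frame")
  df
}

#' Ramp experiment container
#'
#' @param specimen,tank,trajectory domain objects.
#' @param opercular optional `opercular_trace`.
#' @param annotations a `fin_events` data.frame (may be empty).
#' @param t0 ramp start temperature, degC; must match `trajectory$temp` at
#'   t = 0 within 0.1 degC.
#' @param t_loe loss-of-equilibrium temperature, degC; `t_loe > t0`.
#' @param baseline_window numeric length-2, seconds, ending at or before the
#'   ramp start (t = 0).
#' @return a `ramp_experiment` object.
#' @export
ramp_experiment <- function(specimen, tank, trajectory, opercular = NULL,
                            annotations = fin_events(), t0, t_loe,
                            baseline_window = c(-3600, 0)) {
  stopifnot(inherits(specimen, "specimen"), inherits(tank, "tank_geometry"),
            inherits(trajectory, "trajectory"))
  if (t_loe <= t0) stop("t_loe must exceed t0")
  if (baseline_window[2] > 0) stop("baseline window must precede ramp start (t = 0)")
  i0 <- which.min(abs(trajectory$t))
  if (abs(trajectory$temp[i0] - t0) > 0.1)
    stop("t0 does not match trajectory temperature at t = 0 within 0.1 degC")
  structure(
    list(specimen = specimen, tank = tank, trajectory = trajectory,
         opercular = opercular, annotations = annotations,
         t0 = t0, t_loe = t_loe, baseline_window = baseline_window,
         axis = thermal_axis(t0, t_loe)),
    class = "ramp_experiment"
  )
}

#' @export
print.ramp_experiment <- function(x, ...) {
  cat(sprintf("ramp_experiment: %s, BL %.1f cm, T0 %.2f degC -> T_LOE %.2f degC\n",
              x$specimen$species, x$specimen$body_length, x$t0, x$t_loe))
  print(x$trajectory)
  invisible(x)
}

# ---- config -----------------------------------------------------------------

#' Default analysis configuration
#'
#' Every analysis threshold, resolved. Keys:
#' \describe{
#'   \item{frame_rate}{sampling rate, Hz (30).}
#'   \item{px_per_cm}{pixel-to-cm scale for pixel-unit inputs (1 = already cm).}
#'   \item{time_jitter_tol_s}{tolerated timestamp jitter, s (2e-4).}
#'   \item{max_gap_frames}{longest NaN run interpolated rather than rejected (5).}
#'   \item{smooth_window}{position smoothing before linear velocity, frames (5).}
#'   \item{heading_window}{smoothing for the heading channel (1 = none).}
#'   \item{turn_onset_va}{onset threshold for turn detection, deg/s (20).}
#'   \item{turn_offset_va}{hysteresis offset threshold, deg/s (10).}
#'   \item{turn_offset_frames}{frames below offset to close an event (3).}
#'   \item{turn_min_frames}{minimum frames above onset for a candidate (3).}
#'   \item{turn_merge_gap_s}{events closer than this are merged, s (0.5).}
#'   \item{peak_prominence_va}{prominence defining multiple Va peaks, deg/s (15).}
#'   \item{withdrawal_va}{peak |Va| ceiling of withdrawal-like maneuvers (50).}
#'   \item{withdrawal_disp_bl}{backward-displacement floor, BL (0.05).}
#'   \item{sbend_va}{peak |Va| floor of fast S-bends, deg/s (500).}
#'   \item{cmulti_va}{peak |Va| ceiling of multi-stage C-bends, deg/s (100).}
#'   \item{wall_cutoff_bl}{near-wall exclusion distance, BL (0.5).}
#'   \item{laterality_bin_pct}{laterality bin width, %T_LOE (5).}
#'   \item{tally_bin_c}{turn-tally bin width, degC (0.5).}
#'   \item{coupling_bin_c}{coupling-profile bin width, degC (1).}
#'   \item{coupling_window_s}{window around turn onset, s (-0.5, 1.5).}
#'   \item{cycle_prominence_mm}{opercular-cycle minima prominence, mm (0.5).}
#'   \item{cycle_smooth_window}{opercular smoothing window, frames (5).}
#'   \item{open_fraction}{fraction of cycle max defining "fully open" (0.95).}
#'   \item{mask_va}{|Va| above which opercular cycles are masked, deg/s (100).}
#'   \item{fv_window_s}{ventilation tally window, s (60).}
#'   \item{triplet_max_gap_s}{max splay-end to turn-onset gap, s (3).}
#'   \item{glide_min_s}{minimum glide duration, s (0.5).}
#'   \item{seed}{RNG seed for simulation runs.}
#' }
#'
#' @return named list of defaults.
#' @export
default_config <- function() {
  list(
    frame_rate = 30, px_per_cm = 1, time_jitter_tol_s = 2e-4, max_gap_frames = 5,
    smooth_window = 5, heading_window = 1,
    turn_onset_va = 20, turn_offset_va = 10, turn_offset_frames = 3,
    turn_min_frames = 3, turn_merge_gap_s = 0.5, peak_prominence_va = 15,
    withdrawal_va = 50, withdrawal_disp_bl = 0.05, sbend_va = 500, cmulti_va = 100,
    wall_cutoff_bl = 0.5, laterality_bin_pct = 5, tally_bin_c = 0.5,
    coupling_bin_c = 1, coupling_window_s = c(-0.5, 1.5),
    cycle_prominence_mm = 0.5, cycle_smooth_window = 5, open_fraction = 0.95,
    mask_va = 100, fv_window_s = 60, triplet_max_gap_s = 3, glide_min_s = 0.5,
    seed = 1L
  )
}

#' Load a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]. Unknown keys are
#' a hard error (no silent typo tolerance); numeric thresholds and bin widths
#' must be positive where that is required.
#'
#' @param path YAML file; an empty or absent-body file yields all defaults.
#'   File-reference keys (`trajectory_csv`, `opercular_csv`,
#'   `annotations_csv`) and experiment metadata (`species`, `body_length_cm`,
#'   `body_width_cm`, `tank_w_cm`, `tank_l_cm`, `t0_c`, `t_loe_c`,
#'   `baseline_window_s`, `columns`) are passed through.
#' @return a named list (class `ramp_config`).
#' @export
load_config <- function(path) {
  cfg <- default_config()
  meta_keys <- c("trajectory_csv", "opercular_csv", "annotations_csv",
                 "species", "body_length_cm", "body_width_cm",
                 "tank_w_cm", "tank_l_cm", "t0_c", "t_loe_c",
                 "baseline_window_s", "columns")
  user <- if (is.null(path)) NULL else yaml::read_yaml(path)
  if (length(user)) {
    unknown <- setdiff(names(user), c(names(cfg), meta_keys))
    if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  for (k in c("laterality_bin_pct", "tally_bin_c", "coupling_bin_c", "fv_window_s",
              "cycle_prominence_mm", "frame_rate", "px_per_cm")) {
    if (!is.null(cfg[[k]]) && any(cfg[[k]] <= 0)) stop("config key must be positive: ", k)
  }
  class(cfg) <- c("ramp_config", "list")
  cfg
}

# ---- CSV readers ------------------------------------------------------------

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing mandatory column(s) in ", what, ": ", paste(missing, collapse = ", "))
}

.fill_gaps <- function(x, max_gap, what) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  runs <- r$lengths[r$values]
  if (any(runs > max_gap))
    stop("NaN run of ", max(runs), " frames in ", what,
         " exceeds the gap tolerance (", max_gap, ")")
  if (is.na(x[1]) || is.na(x[length(x)]))
    stop("NaN at trajectory boundary in ", what, " cannot be interpolated")
  warning("interpolated ", sum(is.na(x)), " dropped frame(s) in ", what)
  idx <- which(!is.na(x))
  stats::approx(idx, x[idx], xout = seq_along(x))$y
}

#' Read a trajectory CSV
#'
#' Canonical columns: `t_s`, `temp_C`, `x_com_cm`, `y_com_cm`, `x_snout_cm`,
#' `y_snout_cm` (snout optional unless angular analyses are requested).
#' A `columns` mapping (canonical -> vendor name) adapts tracker-export
#' dialects; `px_per_cm` converts pixel-unit coordinates.
#'
#' @param path CSV file (comma-separated, dot decimal, header mandatory).
#' @param cfg a config list (see [load_config()]).
#' @param need_snout require the snout channels (default TRUE).
#' @param tank optional `tank_geometry` for bounds validation.
#' @return a `trajectory`.
#' @export
read_trajectory_csv <- function(path, cfg = default_config(), need_snout = TRUE,
                                tank = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  canon <- c("t_s", "temp_C", "x_com_cm", "y_com_cm", "x_snout_cm", "y_snout_cm")
  map <- cfg$columns
  if (!is.null(map)) {
    for (k in names(map)) names(df)[names(df) == map[[k]]] <- k
  }
  need <- canon[1:4]
  if (need_snout) need <- canon
  .require_columns(df, need, basename(path))
  scale <- cfg$px_per_cm
  gx <- function(col) {
    if (!col %in% names(df)) return(NULL)
    .fill_gaps(df[[col]], cfg$max_gap_frames, col) / scale
  }
  trajectory(
    t = df$t_s, temp = df$temp_C,
    com_x = gx("x_com_cm"), com_y = gx("y_com_cm"),
    snout_x = gx("x_snout_cm"), snout_y = gx("y_snout_cm"),
    frame_rate = cfg$frame_rate, time_jitter_tol_s = cfg$time_jitter_tol_s,
    tank = tank
  )
}

#' Read an opercular head-width CSV (`t_s`, `head_width_mm`)
#'
#' Temperature is interpolated from the trajectory's temperature log.
#'
#' @param path CSV file.
#' @param traj `trajectory` supplying the temperature log.
#' @param cfg config list.
#' @return an `opercular_trace`.
#' @export
read_opercular_csv <- function(path, traj, cfg = default_config()) {
  df <- utils::read.csv(path, check.names = FALSE)
  .require_columns(df, c("t_s", "head_width_mm"), basename(path))
  temp <- stats::approx(traj$t, traj$temp, xout = df$t_s, rule = 2)$y
  opercular_trace(df$t_s, df$head_width_mm, temp, frame_rate = cfg$frame_rate)
}

#' Read a fin/surface annotation CSV (`kind`, `t_start_s`, `t_end_s`, `n_beats`)
#'
#' @param path CSV file.
#' @param traj optional `trajectory` used to attach event temperatures.
#' @return a `fin_events` data.frame.
#' @export
read_annotations_csv <- function(path, traj = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  .require_columns(df, c("kind", "t_start_s", "t_end_s"), basename(path))
  nb <- if ("n_beats" %in% names(df)) df$n_beats else NA_real_
  temp <- NA_real_
  if (!is.null(traj) && nrow(df))
    temp <- stats::approx(traj$t, traj$temp, xout = df$t_start_s, rule = 2)$y
  fin_events(df$kind, df$t_start_s, df$t_end_s, n_beats = nb, temp = temp)
}

#' Read a full experiment from a YAML config
#'
#' The config names the trajectory CSV (mandatory), optional opercular and
#' annotation CSVs, specimen metadata and tank geometry. Missing optional
#' streams yield empty-but-typed fields.
#'
#' @param config_path YAML file (see [load_config()]).
#' @return a `ramp_experiment` with the resolved config attached as
#'   `attr(, "config")`.
#' @export
read_experiment <- function(config_path) {
  cfg <- load_config(config_path)
  if (is.null(cfg$trajectory_csv)) stop("config must name `trajectory_csv`")
  base <- dirname(config_path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  tank <- tank_geometry(cfg$tank_w_cm %||% 93, cfg$tank_l_cm %||% 93)
  spec <- specimen(cfg$species %||% "HB_PLUS",
                   cfg$body_length_cm, cfg$body_width_cm)
  traj <- read_trajectory_csv(resolve(cfg$trajectory_csv), cfg, tank = tank)
  op <- NULL
  if (!is.null(cfg$opercular_csv))
    op <- read_opercular_csv(resolve(cfg$opercular_csv), traj, cfg)
  ann <- fin_events()
  if (!is.null(cfg$annotations_csv))
    ann <- read_annotations_csv(resolve(cfg$annotations_csv), traj)
  i0 <- which.min(abs(traj$t))
  ex <- ramp_experiment(
    specimen = spec, tank = tank, trajectory = traj, opercular = op,
    annotations = ann,
    t0 = cfg$t0_c %||% traj$temp[i0],
    t_loe = cfg$t_loe_c %||% max(traj$temp),
    baseline_window = as.numeric(cfg$baseline_window_s %||% c(min(traj$t), 0))
  )
  attr(ex, "config") <- cfg
  ex
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- results writer ---------------------------------------------------------

#' Write result tables and a run manifest
#'
#' Writes each table in `bundle` (a named list of data.frames) as a TSV under
#' `out_dir`, plus `manifest.json` recording the package version, seed,
#' config hash and table checksums. Overwrites are idempotent: the same
#' bundle always produces byte-identical files.
#'
#' @param bundle named list of data.frames (at least one).
#' @param out_dir output directory (created if needed).
#' @param seed seed recorded in the manifest.
#' @param config config list recorded (hashed) in the manifest.
#' @return invisibly, the paths written.
#' @export
write_results <- function(bundle, out_dir, seed = NA_integer_, config = NULL) {
  if (!length(bundle) || !any(vapply(bundle, is.data.frame, logical(1))))
    stop("nothing to write: bundle contains no tables")
  if (is.null(names(bundle)) || any(names(bundle) == ""))
    stop("bundle tables must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("output directory is not writable: ", out_dir)
  paths <- character(0)
  for (nm in names(bundle)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(bundle[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "rampetho",
    version = as.character(utils::packageVersion("rampetho")),
    seed = seed,
    config_hash = if (is.null(config)) NA_character_ else
      unname(tools::md5sum(textConnection_md5(config))),
    tables = as.list(unname(Map(function(p) unname(tools::md5sum(p)), paths))),
    files = basename(paths)
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

# md5 of a config's deparsed form via a temp file (tools::md5sum wants a path)
textConnection_md5 <- function(config) {
  tf <- tempfile(fileext = ".txt")
  writeLines(paste(utils::capture.output(utils::str(config)), collapse = "\n"), tf)
  tf
}

#' Read back a written result table at full precision
#'
#' @param path TSV written by [write_results()].
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}
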