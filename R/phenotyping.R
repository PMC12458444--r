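#' Classify each minute of a trajectory as active or inactive
#'
#' Follows the minute-binned convention of Drosophila activity monitoring:
#' minute m (covering `[60*(m-1), 60*m)` seconds within the scored window)
#' is active iff the summed per-sample displacement in it exceeds
#' `epsilon_mm`. A partial trailing minute is dropped.
#'
#' @param traj A [fly_trajectory()].
#' @param epsilon_mm Displacement threshold in mm (default 1, a standard
#'   inactivity criterion for tube assays).
#' @param window_s Optional `c(start, end)` in seconds restricting the
#'   scored window (samples with `start <= t < end`); default the whole
#'   recording.
#' @return Logical vector, one element per complete minute; `TRUE` =
#'   active.
#' @export
binarize_activity <- function(traj, epsilon_mm = 1, window_s = NULL) {
  stopifnot(inherits(traj, "fly_trajectory"))
  if (epsilon_mm < 0) stop("epsilon_mm must be non-negative")
  t <- traj$times
  sp <- traj$speeds
  if (!is.null(window_s)) {
    keep <- t >= window_s[1L] & t < window_s[2L]
    t <- t[keep] - window_s[1L]
    sp <- sp[keep]
  }
  span <- length(t) * traj$dt_s
  if (span < 60) stop("scored window must cover at least one full minute")
  n_min <- floor(span / 60)
  minute <- floor(t / 60) + 1L
  keep <- minute <= n_min
  disp <- vapply(split(sp[keep] * traj$dt_s, minute[keep]), sum, numeric(1))
  # minutes with no samples (cannot happen on a uniform grid) would be NA
  out <- rep(FALSE, n_min)
  out[as.integer(names(disp))] <- disp > epsilon_mm
  out
}

#' Detect sleep bouts from per-minute activity flags
#'
#' A sleep bout is a maximal run of consecutive inactive minutes lasting at
#' least `min_bout_min` minutes (inclusive threshold: a 5-minute run counts
#' at the default).
#'
#' @param active Logical per-minute flags (`TRUE` = active).
#' @param min_bout_min Minimum bout length in minutes (default 5).
#' @return Data.frame with columns `start_s`, `end_s`, `duration_min`;
#'   zero rows when no bout qualifies.
#' @export
detect_sleep_bouts <- function(active, min_bout_min = 5) {
  if (min_bout_min < 1) stop("min_bout_min must be >= 1")
  active <- as.logical(active)
  if (anyNA(active)) stop("activity flags must not contain NA")
  r <- rle(!active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_bout_min
  data.frame(start_s = (starts[keep] - 1L) * 60,
             end_s = ends[keep] * 60,
             duration_min = r$lengths[keep])
}

#' Average sleep minutes per hour within a scoring window
#'
#' @param bouts Bout table from [detect_sleep_bouts()].
#' @param window_duration_s Length of the scored window in seconds.
#' @return Minutes asleep per hour, in `[0, 60]`.
#' @export
sleep_minutes_per_hour <- function(bouts, window_duration_s) {
  if (window_duration_s <= 0) stop("window_duration_s must be positive")
  if (nrow(bouts) && any(bouts$end_s > window_duration_s + 1e-9))
    stop("bout extends beyond the scoring window")
  sum(bouts$duration_min) / (window_duration_s / 3600)
}

#' Baseline locomotor speed in the pre-stimulus hour
#'
#' Mean of the derived speeds over the hour before the stimulus, in mm/s.
#' Because each speed is aligned to the later sample of its displacement,
#' the scored samples are those in `(first_stimulus_s - 3600,
#' first_stimulus_s]`, which makes the result exactly the path length
#' covered during the hour divided by 3600 s.
#'
#' @param traj A [fly_trajectory()].
#' @param first_stimulus_s Onset of the first stimulus (>= 3600 s).
#' @return Mean speed in mm/s.
#' @export
baseline_speed <- function(traj, first_stimulus_s) {
  stopifnot(inherits(traj, "fly_trajectory"))
  if (first_stimulus_s < 3600)
    stop("insufficient pre-stimulus data: first stimulus before 3600 s")
  keep <- traj$times > first_stimulus_s - 3600 & traj$times <= first_stimulus_s
  n_expected <- round(3600 / traj$dt_s)
  if (sum(keep) < n_expected)
    stop("insufficient pre-stimulus data: baseline hour not fully recorded")
  mean(traj$speeds[keep])
}

#' Duration of the startle response after one stimulus
#'
#' Smooths the post-stimulus speed trace with a right-aligned rolling mean
#' (window `smooth_window_s`) and returns the elapsed time from the
#' stimulus to the first sample at which the smoothed speed has returned to
#' (i.e. is at or below) the fly's baseline speed. If the very first
#' post-stimulus sample is already at or below baseline the duration is 0.
#' If no return occurs within `cap_s` the value is right-censored at
#' `cap_s`.
#'
#' @param traj A [fly_trajectory()].
#' @param stim_s Stimulus onset (s), within the recording.
#' @param baseline Baseline speed in mm/s (>= 0).
#' @param smooth_window_s Rolling-mean window (s), default 10.
#' @param cap_s Censoring horizon in seconds after the stimulus; default
#'   the remainder of the recording. Callers scoring several stimuli
#'   should cap at the next stimulus to avoid overlapping windows.
#' @return List with `duration_s` and logical `censored`.
#' @export
startle_duration <- function(traj, stim_s, baseline, smooth_window_s = 10,
                             cap_s = NULL) {
  stopifnot(inherits(traj, "fly_trajectory"))
  if (baseline < 0) stop("baseline speed must be non-negative")
  t_end <- traj$times[length(traj$times)]
  if (stim_s < 0 || stim_s >= t_end) stop("stimulus outside the recording")
  if (is.null(cap_s)) cap_s <- t_end - stim_s
  idx <- which(traj$times > stim_s & traj$times <= stim_s + cap_s)
  if (!length(idx)) stop("no post-stimulus samples before the cap")
  w <- max(1L, round(smooth_window_s / traj$dt_s))
  smoothed <- rolling_mean_right(traj$speeds[idx], w)
  hit <- which(smoothed <= baseline)
  if (!length(hit))
    return(list(duration_s = cap_s, censored = TRUE))
  first <- hit[1L]
  dur <- if (first == 1L) 0 else traj$times[idx[first]] - stim_s
  list(duration_s = dur, censored = FALSE)
}

#' Magnitude of the startle response after one stimulus
#'
#' Mean derived speed over the minute after the stimulus minus the
#' baseline speed (mm/s; may be negative).
#'
#' @inheritParams startle_duration
#' @return Speed difference in mm/s.
#' @export
startle_magnitude <- function(traj, stim_s, baseline) {
  stopifnot(inherits(traj, "fly_trajectory"))
  idx <- which(traj$times > stim_s & traj$times <= stim_s + 60)
  if (length(idx) < round(60 / traj$dt_s))
    stop("post-stimulus minute truncated by end of recording")
  mean(traj$speeds[idx]) - baseline
}

#' Aggregate per-stimulus startle values to one value per fly
#'
#' The mean across stimuli; censored durations enter at their cap value
#' (dropping them would bias durations downward).
#'
#' @param values Numeric per-stimulus values.
#' @return Their mean.
#' @export
aggregate_startle <- function(values) {
  if (!length(values)) stop("no per-stimulus values to aggregate")
  mean(values)
}

#' Occupancy of equal-length tube zones
#'
#' Divides the tube into `n_zones` equal-length regions with half-open
#' bins `[i*L/n, (i+1)*L/n)` (a position exactly at `L` goes to the last
#' zone) and returns the proportion of samples in each. Zone 1 is
#' adjacent to the food (position 0); zone `n_zones` is the far end.
#'
#' @param traj A [fly_trajectory()].
#' @param n_zones Number of zones (default 8).
#' @param window_s Optional `c(start, end)` scoring window in seconds
#'   (samples with `start <= t < end`); default the whole recording.
#' @return Numeric vector of `n_zones` proportions summing to 1.
#' @export
zone_occupancy <- function(traj, n_zones = 8, window_s = NULL) {
  stopifnot(inherits(traj, "fly_trajectory"))
  L <- traj$tube_length_mm
  if (L <= 0) stop("tube length must be positive")
  x <- traj$positions
  if (!is.null(window_s))
    x <- x[traj$times >= window_s[1L] & traj$times < window_s[2L]]
  if (!length(x)) stop("no samples in the scoring window")
  zone <- pmin(floor(n_zones * x / L), n_zones - 1)
  as.numeric(tabulate(zone + 1L, nbins = n_zones)) / length(x)
}

#' Arcsine-square-root transform for proportion traits
#'
#' The variance-stabilizing map `p -> asin(sqrt(p))`, applied to
#' proportion traits before linear modeling.
#'
#' @param p Proportions in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsin_sqrt <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("proportions must lie in [0, 1]")
  asin(sqrt(p))
}

#' Compute the six behavioral traits for every fly
#'
#' Per fly: sleep minutes per hour over the pre-stimulus period (5-minute
#' inactivity bouts on minute bins), baseline speed over the pre-stimulus
#' hour, startle duration and magnitude averaged over stimuli (durations
#' right-censored at the next stimulus), and the proportion of baseline-
#' hour samples in the food-adjacent and far zones of an 8-zone division.
#'
#' @param trajectories Named list of [fly_trajectory()] objects.
#' @param design The [assay_design()] used to record them.
#' @param epsilon_mm Per-minute displacement threshold for inactivity.
#' @param min_bout_min Minimum sleep-bout length (minutes).
#' @param smooth_window_s Rolling-mean window for startle duration.
#' @param n_zones Number of tube zones.
#' @param occupancy_window `"baseline"` (pre-stimulus hour, default) or
#'   `"full"` recording.
#' @return Data.frame with columns `fly_id`, the six traits, and
#'   `n_censored_startles`.
#' @export
compute_phenotypes <- function(trajectories, design,
                               epsilon_mm = 1, min_bout_min = 5,
                               smooth_window_s = 10, n_zones = 8,
                               occupancy_window = c("baseline", "full")) {
  stopifnot(inherits(design, "assay_design"))
  occupancy_window <- match.arg(occupancy_window)
  stim <- design$stimulus_times_s
  first_stim <- stim[1L]
  caps <- c(diff(stim), design$recording_duration_s - stim[length(stim)])

  rows <- lapply(trajectories, function(tr) {
    active <- binarize_activity(tr, epsilon_mm, window_s = c(0, first_stim))
    bouts <- detect_sleep_bouts(active, min_bout_min)
    sleep <- sleep_minutes_per_hour(bouts, length(active) * 60)

    base <- baseline_speed(tr, first_stim)

    durs <- numeric(length(stim))
    cens <- logical(length(stim))
    mags <- numeric(length(stim))
    for (k in seq_along(stim)) {
      d <- startle_duration(tr, stim[k], base, smooth_window_s,
                            cap_s = caps[k])
      durs[k] <- d$duration_s
      cens[k] <- d$censored
      mags[k] <- startle_magnitude(tr, stim[k], base)
    }

    win <- if (occupancy_window == "baseline")
      c(first_stim - 3600, first_stim) else NULL
    zones <- zone_occupancy(tr, n_zones, window_s = win)

    data.frame(fly_id = tr$fly_id,
               sleep_min_per_hour = sleep,
               base_speed_mm_s = base,
               startle_duration_s = aggregate_startle(durs),
               startle_magnitude_mm_s = aggregate_startle(mags),
               prop_near_food = zones[1L],
               prop_far_food = zones[n_zones],
               n_censored_startles = sum(cens),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
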