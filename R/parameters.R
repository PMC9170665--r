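#' Task parameters for an anticipated response inhibition session
#'
#' Builds and validates the full set of tunable constants governing a
#' session: trial timing, bar geometry, the anticipation target, the go-trial
#' feedback bands, and the stop-signal-delay (SSD) staircase.  Defaults follow
#' the standard OSARI configuration: a 3 x 15 cm bar filling over a 1 s trial,
#' a target at 80% of bar height (so the planned lift falls at 800 ms),
#' feedback bands at 20/40/60 ms of error, and a 1-up/1-down staircase
#' starting at 500 ms with 25 ms steps clamped to [50, 775] ms.
#'
#' @param trial_duration trial length in seconds; the bar takes this long to
#'   fill from bottom to top.
#' @param bar_height,bar_width bar geometry in cm.
#' @param target_fraction fraction of bar height at which the target sits,
#'   strictly between 0 and 1.  The planned go response occurs when the bar
#'   reaches the target, i.e. at `trial_duration * target_fraction` seconds.
#' @param feedback_bands three strictly increasing positive thresholds (ms).
#'   Go responses within the first threshold of the target earn "green",
#'   within the second "yellow", within the third "orange", beyond it "red".
#' @param initial_ssd staircase starting SSD in ms.
#' @param step_size staircase step in ms (added after a successful stop,
#'   subtracted after a failed one).
#' @param min_ssd,max_ssd hard clamps on the SSD in ms.  Both must lie inside
#'   the trial, and `min_ssd <= initial_ssd <= max_ssd`.
#' @param early_lift_window lifts within this many ms of fill onset are
#'   flagged with an encouragement message (the trial still counts).
#' @param start_interval_range length-2 numeric, seconds: bounds of the
#'   uniformly drawn hold interval between key press and fill onset.
#' @param ssd_mode `"staircase"` (adaptive) or `"fixed"` (SSDs taken from the
#'   condition table's `fixedStopTime` column).
#' @param trial_order `"random"` (seeded permutation) or `"sequential"`
#'   (condition-table row order).
#'
#' @return An object of class `osari_params` (a validated named list).
#' @examples
#' p <- task_parameters()
#' target_time(p)           # 0.8 s
#' @export
task_parameters <- function(trial_duration = 1.0,
                            bar_height = 15,
                            bar_width = 3,
                            target_fraction = 0.8,
                            feedback_bands = c(20, 40, 60),
                            initial_ssd = 500,
                            step_size = 25,
                            min_ssd = 50,
                            max_ssd = 775,
                            early_lift_window = 100,
                            start_interval_range = c(0.5, 1.0),
                            ssd_mode = c("staircase", "fixed"),
                            trial_order = c("random", "sequential")) {
  ssd_mode <- match.arg(ssd_mode)
  trial_order <- match.arg(trial_order)

  stopifnot(
    "trial_duration must be a positive number" =
      is.numeric(trial_duration) && length(trial_duration) == 1 && trial_duration > 0,
    "bar_height must be positive" = is.numeric(bar_height) && bar_height > 0,
    "bar_width must be positive" = is.numeric(bar_width) && bar_width > 0,
    "target_fraction must lie strictly between 0 and 1" =
      is.numeric(target_fraction) && target_fraction > 0 && target_fraction < 1,
    "feedback_bands must be three positive strictly increasing thresholds" =
      is.numeric(feedback_bands) && length(feedback_bands) == 3 &&
        all(feedback_bands > 0) && all(diff(feedback_bands) > 0),
    "step_size must be positive" = is.numeric(step_size) && step_size > 0,
    "early_lift_window must be non-negative" =
      is.numeric(early_lift_window) && early_lift_window >= 0,
    "start_interval_range must be two non-decreasing non-negative seconds" =
      is.numeric(start_interval_range) && length(start_interval_range) == 2 &&
        start_interval_range[1] >= 0 &&
        start_interval_range[2] >= start_interval_range[1]
  )

  trial_ms <- trial_duration * 1000
  if (!(min_ssd > 0 && max_ssd < trial_ms)) {
    stop("SSD clamps must lie strictly inside (0, ", trial_ms, ") ms")
  }
  if (!(min_ssd <= initial_ssd && initial_ssd <= max_ssd)) {
    stop("initial_ssd must satisfy min_ssd <= initial_ssd <= max_ssd")
  }

  structure(
    list(
      trial_duration = trial_duration,
      bar_height = bar_height,
      bar_width = bar_width,
      target_fraction = target_fraction,
      feedback_bands = feedback_bands,
      initial_ssd = initial_ssd,
      step_size = step_size,
      min_ssd = min_ssd,
      max_ssd = max_ssd,
      early_lift_window = early_lift_window,
      start_interval_range = start_interval_range,
      ssd_mode = ssd_mode,
      trial_order = trial_order
    ),
    class = "osari_params"
  )
}

#' @export
print.osari_params <- function(x, ...) {
  cat("Anticipated response inhibition task parameters\n")
  cat(sprintf("  trial duration : %g s (bar %g x %g cm)\n",
              x$trial_duration, x$bar_width, x$bar_height))
  cat(sprintf("  target         : %g%% of bar height (t = %g s)\n",
              100 * x$target_fraction, target_time(x)))
  cat(sprintf("  feedback bands : %s ms\n",
              paste(x$feedback_bands, collapse = "/")))
  cat(sprintf("  SSD            : %s, start %g ms, step %g ms, clamps [%g, %g] ms\n",
              x$ssd_mode, x$initial_ssd, x$step_size, x$min_ssd, x$max_ssd))
  invisible(x)
}

#' Time at which the filling bar reaches the target
#'
#' @param params an [task_parameters()] object.
#' @return Seconds from fill onset: `trial_duration * target_fraction`.
#' @export
target_time <- function(params) {
  params$trial_duration * params$target_fraction
}

#' Height of the filling bar at a given elapsed time
#'
#' Time-approach rendering arithmetic: the bar height is proportional to the
#' elapsed fraction of the trial, capped at the full bar height.
#'
#' @param elapsed non-negative seconds since fill onset (vectorised).
#' @param params an [task_parameters()] object.
#' @return Bar height in cm: `bar_height * elapsed / trial_duration`, capped.
#' @examples
#' bar_position(0.337, task_parameters())  # 5.055 cm
#' @export
bar_position <- function(elapsed, params) {
  if (any(elapsed < 0)) stop("elapsed time must be non-negative")
  pmin(params$bar_height * elapsed / params$trial_duration, params$bar_height)
}

#' Distance the filling bar travels per screen refresh
#'
#' Space-approach rendering arithmetic: the per-frame increment at a fixed
#' refresh rate.
#'
#' @param refresh_rate screen refresh rate in Hz, strictly positive.
#' @param params an [task_parameters()] object.
#' @return cm per frame: `bar_height * (1/refresh_rate) / trial_duration`.
#' @examples
#' distance_per_frame(60, task_parameters())  # 0.25 cm
#' @export
distance_per_frame <- function(refresh_rate, params) {
  if (any(refresh_rate <= 0)) stop("refresh_rate must be strictly positive")
  params$bar_height * (1 / refresh_rate) / params$trial_duration
}
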