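#' Generative participant parameters for the horse-race simulator
#'
#' The independent horse-race account treats every stop trial as a race
#' between a go process (the planned anticipated lift) and a stop process
#' launched when the bar halts.  The simulator draws both finishing times
#' from Normal distributions truncated to positive values: the go finishing
#' time is the planned lift time measured from fill onset (so its mean sits
#' near the target time), the stop finishing time is the stop-signal
#' reaction time (SSRT) measured from the moment the bar stops.
#'
#' @param go_mean,go_sd mean and SD of the go finishing time, seconds.  Lift
#'   times drawn beyond the trial duration become omissions.
#' @param ssrt_mean,ssrt_sd mean and SD of the stop finishing time (SSRT),
#'   seconds.
#' @param p_trigger_failure probability that the stop process is never
#'   launched on a stop trial, in which case the go process runs unopposed.
#' @param p_start_interval_lift probability, per attempted start, of lifting
#'   during the variable start interval (aborting and restarting the trial).
#' @return An object of class `osari_participant`.
#' @export
participant_params <- function(go_mean = 0.8, go_sd = 0.05,
                               ssrt_mean = 0.2, ssrt_sd = 0.03,
                               p_trigger_failure = 0,
                               p_start_interval_lift = 0) {
  stopifnot(
    "go_mean must be positive" = is.numeric(go_mean) && go_mean > 0,
    "go_sd must be non-negative" = is.numeric(go_sd) && go_sd >= 0,
    "ssrt_mean must be non-negative" = is.numeric(ssrt_mean) && ssrt_mean >= 0,
    "ssrt_sd must be non-negative" = is.numeric(ssrt_sd) && ssrt_sd >= 0,
    "p_trigger_failure must be a probability" =
      p_trigger_failure >= 0 && p_trigger_failure <= 1,
    "p_start_interval_lift must be a probability" =
      p_start_interval_lift >= 0 && p_start_interval_lift < 1
  )
  structure(
    list(go_mean = go_mean, go_sd = go_sd,
         ssrt_mean = ssrt_mean, ssrt_sd = ssrt_sd,
         p_trigger_failure = p_trigger_failure,
         p_start_interval_lift = p_start_interval_lift),
    class = "osari_participant"
  )
}

#' @export
print.osari_participant <- function(x, ...) {
  cat(sprintf(
    "<race-model participant: go ~ N(%g, %g) s, SSRT ~ N(%g, %g) s%s>\n",
    x$go_mean, x$go_sd, x$ssrt_mean, x$ssrt_sd,
    if (x$p_trigger_failure > 0) {
      sprintf(", P(trigger failure) = %g", x$p_trigger_failure)
    } else ""))
  invisible(x)
}

# Normal truncated to (0, Inf) by rejection; exact for sd = 0.
rtruncnorm_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Draw go-process finishing times
#'
#' Samples planned lift times from the participant's truncated-Normal go
#' distribution.  Values beyond the trial duration are returned as drawn and
#' denote "no lift before trial end" (a go omission) downstream.
#'
#' @param participant an [participant_params()] object.
#' @param n number of draws.
#' @return numeric vector of finishing times, seconds.
#' @export
draw_go_finish <- function(participant, n = 1) {
  rtruncnorm_pos(n, participant$go_mean, participant$go_sd)
}

#' Resolve one stop-trial race
#'
#' Given realised finishing times, decides whether the response escapes
#' inhibition: if the stop process was triggered, the response is made iff
#' the go process finishes no later than `ssd + t_stop` (the go process
#' wins exact ties); if the trigger failed, the go process runs unopposed.
#'
#' @param t_go go finishing time, seconds from fill onset.
#' @param ssd stop-signal delay, seconds.
#' @param t_stop stop finishing time (SSRT), seconds from the stop signal.
#' @param triggered was the stop process launched?
#' @param trial_duration trial length, seconds; a winning go process that
#'   finishes after it is an omission (no response).
#' @return list with `responded` (logical) and `rt` (seconds, `NA` when no
#'   response is made).
#' @examples
#' simulate_stop_trial(0.78, 0.65, 0.12)  # stop wins: 0.77 < 0.78
#' simulate_stop_trial(0.76, 0.65, 0.12)  # go wins: responds at 0.76 s
#' @export
simulate_stop_trial <- function(t_go, ssd, t_stop, triggered = TRUE,
                                trial_duration = 1.0) {
  stopifnot(ssd >= 0, t_stop >= 0)
  go_wins <- if (triggered) t_go <= ssd + t_stop else TRUE  # go wins ties
  if (go_wins && t_go <= trial_duration) {
    list(responded = TRUE, rt = t_go)
  } else {
    list(responded = FALSE, rt = NA_real_)
  }
}

#' Build a race-model responder for [run_session()]
#'
#' Wraps a participant in the responder interface: on every trial it draws
#' the number of start-interval false starts (geometric in
#' `p_start_interval_lift`), then a go finishing time; on stop trials it
#' additionally draws the trigger and the stop finishing time and resolves
#' the race.  By construction the go finishing-time distribution is the same
#' on go and stop trials (context independence).
#'
#' @param participant an [participant_params()] object.
#' @param params an [task_parameters()] object.
#' @return a responder function, see [run_session()].
#' @export
race_responder <- function(participant, params) {
  force(participant); force(params)
  function(trial, ssd) {
    restarts <- if (participant$p_start_interval_lift > 0) {
      stats::rgeom(1, 1 - participant$p_start_interval_lift)
    } else 0L
    t_go <- draw_go_finish(participant)
    if (trial$signal == 0) {
      return(list(lift = t_go, restarts = restarts))
    }
    triggered <- if (participant$p_trigger_failure > 0) {
      stats::runif(1) >= participant$p_trigger_failure
    } else TRUE
    t_stop <- rtruncnorm_pos(1, participant$ssrt_mean, participant$ssrt_sd)
    race <- simulate_stop_trial(t_go, ssd, t_stop, triggered,
                                params$trial_duration)
    list(lift = if (race$responded) race$rt else NA_real_,
         restarts = restarts)
  }
}

#' Simulate a full session for one participant
#'
#' Composes [run_session()] with [race_responder()]: the standard way to
#' produce realistic task data without a human.
#'
#' @param participant an [participant_params()] object.
#' @param params an [task_parameters()] object.
#' @param session list of blocks; defaults to [default_session()].
#' @param seed integer seed; the session is exactly reproducible given it.
#' @param id participant identifier; when `path` is given it is written into
#'   the data file.
#' @param path optional file path; when given, the session is also written
#'   in the trial-level `.txt` format via [write_trials()].
#' @return the trial data frame from [run_session()]; when `path` is given
#'   the file is written as a side effect.
#' @export
simulate_session <- function(participant, params = task_parameters(),
                             session = default_session(params),
                             seed = NULL, id = "sim", path = NULL) {
  trials <- run_session(session, race_responder(participant, params),
                        params, seed = seed)
  trials <- cbind(data.frame(id = rep(id, nrow(trials)),
                             stringsAsFactors = FALSE), trials)
  if (!is.null(path)) {
    write_trials(trials, path, id = id)
  }
  trials
}

#' Simulate a cohort of participants
#'
#' Draws per-participant generative parameters from uniform hyper-ranges,
#' simulates one session each, and (optionally) writes one data file per
#' participant plus a manifest of the true parameters -- the setup for
#' parameter-recovery studies.
#'
#' @param n_participants cohort size.
#' @param master_seed integer; per-participant seeds are derived from it.
#' @param params an [task_parameters()] object.
#' @param session list of blocks; defaults to [default_session()].
#' @param go_mean_range,go_sd_range,ssrt_mean_range,ssrt_sd_range length-2
#'   numeric ranges the true parameters are drawn from (degenerate ranges
#'   fix a parameter).
#' @param out_dir optional directory; when given, writes
#'   `<id>_OSARI_<timestamp>.txt` per participant and `manifest.txt`
#'   (participant id, seed and true parameters).
#' @param timestamp `POSIXct` used for file naming (defaults to now).
#' @return list with `manifest` (data frame of true parameters, plus a
#'   `file` column when files were written) and `sessions` (list of trial
#'   data frames, named by participant id).
#' @export
simulate_cohort <- function(n_participants, master_seed,
                            params = task_parameters(),
                            session = default_session(params),
                            go_mean_range = c(0.75, 0.85),
                            go_sd_range = c(0.03, 0.07),
                            ssrt_mean_range = c(0.15, 0.25),
                            ssrt_sd_range = c(0.02, 0.04),
                            out_dir = NULL, timestamp = Sys.time()) {
  stopifnot(n_participants >= 1)
  draws <- with_seed(master_seed, data.frame(
    go_mean = stats::runif(n_participants, go_mean_range[1], go_mean_range[2]),
    go_sd = stats::runif(n_participants, go_sd_range[1], go_sd_range[2]),
    ssrt_mean = stats::runif(n_participants, ssrt_mean_range[1],
                             ssrt_mean_range[2]),
    ssrt_sd = stats::runif(n_participants, ssrt_sd_range[1], ssrt_sd_range[2])
  ))
  seeds <- derive_seeds(master_seed + 1, n_participants)
  ids <- sprintf("sim%03d", seq_len(n_participants))
  manifest <- cbind(data.frame(id = ids, seed = seeds,
                               stringsAsFactors = FALSE), draws)
  sessions <- vector("list", n_participants)
  names(sessions) <- ids
  files <- character(n_participants)
  for (i in seq_len(n_participants)) {
    part <- participant_params(go_mean = draws$go_mean[i],
                               go_sd = draws$go_sd[i],
                               ssrt_mean = draws$ssrt_mean[i],
                               ssrt_sd = draws$ssrt_sd[i])
    trials <- simulate_session(part, params, session, seed = seeds[i],
                               id = ids[i])
    sessions[[i]] <- trials
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      files[i] <- file.path(out_dir,
                            paste0(build_filename(ids[i], timestamp), ".txt"))
      if (file.exists(files[i])) {
        stop("refusing to overwrite existing data file: ", files[i])
      }
      write_trials(trials, files[i], id = ids[i])
    }
  }
  if (!is.null(out_dir)) {
    manifest$file <- basename(files)
    manifest_path <- file.path(out_dir, "manifest.txt")
    utils::write.table(manifest, manifest_path, sep = " ", quote = FALSE,
                       row.names = FALSE)
  }
  list(manifest = manifest, sessions = sessions)
}
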