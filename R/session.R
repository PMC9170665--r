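#' Run a session of scheduled blocks against a responder
#'
#' The deterministic heart of the task: walks the blocks in order,
#' schedules each one, maintains the SSD staircase, asks the `responder`
#' what the participant's finger did on every trial, and classifies the
#' outcome.  No graphics, no clocks -- given the same seed and responder the
#' result is bit-identical.
#'
#' The staircase is initialised to `initial_ssd` at the start of the
#' practice mixed block and re-initialised at the first test mixed block;
#' it then carries across the remaining test mixed blocks (practice
#' performance never leaks into the test blocks).  In fixed-SSD mode each
#' stop trial instead uses its `planned_ssd` from the condition table.
#'
#' One seeded RNG stream drives the whole session; draws occur in a fixed
#' order (per block: the trial permutation; per trial: the variable start
#' interval, then any draws the responder makes), so sessions are exactly
#' reproducible.
#'
#' @param session a list of [block_spec()] objects (or a single one), e.g.
#'   from [default_session()].
#' @param responder a function `function(trial, ssd)` describing the
#'   participant.  `trial` is a list with `trialType`, `trial`, `signal`;
#'   `ssd` is the stop-signal delay in seconds (`NA` on go trials).  It
#'   must return a list with `lift` (key-release time in seconds from fill
#'   onset, or `NA` for no lift before trial end) and optionally `restarts`
#'   (number of aborted starts due to lifts during the start interval;
#'   these do not consume a trial).
#' @param params an [task_parameters()] object.
#' @param seed optional integer; when given, the session runs under its own
#'   seeded RNG stream and the caller's RNG state is untouched.
#' @return A data frame with one row per scheduled trial:
#'   `block` (1-based index among blocks of the same type), `trialType`,
#'   `trial` (index within block), `signal` (0 go / 1 stop),
#'   `response` (1 lifted / 0 held), `ssd` (seconds; `NA` on go trials),
#'   `rt` (seconds from fill onset; `NA` for omissions and successful
#'   stops), `feedback` (colour band; `NA` for go omissions),
#'   `early_lift_restarts`, `encouragement` (lift within the early-lift
#'   window of fill onset) and `start_interval` (drawn hold time, seconds).
#' @export
run_session <- function(session, responder, params, seed = NULL) {
  if (inherits(session, "osari_block")) session <- list(session)
  if (!length(session)) stop("session must contain at least one block")
  if (!all(vapply(session, inherits, logical(1), "osari_block"))) {
    stop("session must be a list of block_spec() objects")
  }
  if (!is.function(responder)) stop("responder must be a function")

  if (!is.null(seed)) {
    return(with_seed(seed, run_session(session, responder, params)))
  }

  ssd_ms <- NA_real_          # staircase state, ms
  test_reset_done <- FALSE
  type_counts <- stats::setNames(integer(length(block_labels)), block_labels)
  rows <- vector("list", length(session))

  for (b in seq_along(session)) {
    spec <- session[[b]]
    label <- spec$label
    type_counts[label] <- type_counts[label] + 1L

    if (identical(label, "practiceMixed")) {
      ssd_ms <- params$initial_ssd
    } else if (identical(label, "testMixed") && !test_reset_done) {
      ssd_ms <- params$initial_ssd
      test_reset_done <- TRUE
    }

    sched <- schedule_block(spec, order = params$trial_order)
    n <- nrow(sched)
    out <- data.frame(
      block = rep(type_counts[[label]], n),
      trialType = sched$trialType,
      trial = sched$trial,
      signal = sched$signal,
      response = NA_integer_,
      ssd = NA_real_,
      rt = NA_real_,
      feedback = NA_character_,
      early_lift_restarts = NA_integer_,
      encouragement = NA,
      start_interval = NA_real_,
      stringsAsFactors = FALSE
    )

    for (i in seq_len(n)) {
      out$start_interval[i] <- stats::runif(1, params$start_interval_range[1],
                                            params$start_interval_range[2])
      is_stop <- sched$signal[i] == 1L
      ssd_s <- NA_real_
      if (is_stop) {
        if (params$ssd_mode == "fixed") {
          planned <- sched$planned_ssd[i]
          if (is.na(planned)) {
            stop("fixed-SSD mode requires a fixedStopTime for every stop trial (",
                 label, " block ", type_counts[[label]], ", trial ", i, ")")
          }
          if (planned < params$min_ssd || planned > params$max_ssd) {
            stop("fixedStopTime ", planned, " ms outside [",
                 params$min_ssd, ", ", params$max_ssd, "] ms")
          }
          ssd_s <- planned / 1000
        } else {
          if (is.na(ssd_ms)) ssd_ms <- params$initial_ssd
          ssd_s <- ssd_ms / 1000
        }
      }

      trial_info <- list(trialType = label, trial = i,
                         signal = sched$signal[i])
      resp <- tryCatch(
        responder(trial_info, ssd_s),
        error = function(e) {
          stop("responder failed on ", label, " block ",
               type_counts[[label]], ", trial ", i, ": ",
               conditionMessage(e))
        }
      )
      lift <- resp$lift
      if (is.null(lift)) lift <- NA_real_
      restarts <- as.integer(resp$restarts %||% 0L)
      if (!is.na(lift) && lift <= 0) {
        stop("responder returned a non-positive lift time on ", label,
             " block ", type_counts[[label]], ", trial ", i)
      }
      lifted <- !is.na(lift) && lift <= params$trial_duration

      out$early_lift_restarts[i] <- restarts
      out$encouragement[i] <- lifted &&
        lift <= params$early_lift_window / 1000

      if (!is_stop) {
        if (lifted) {
          out$response[i] <- 1L
          out$rt[i] <- lift
          out$feedback[i] <- classify_go_feedback(lift, params)
        } else {
          out$response[i] <- 0L        # omission: no lift before fill
        }
      } else {
        out$ssd[i] <- ssd_s
        if (lifted) {
          out$response[i] <- 1L
          out$rt[i] <- lift
          out$feedback[i] <- "red"
        } else {
          out$response[i] <- 0L
          out$feedback[i] <- "green"
        }
        if (params$ssd_mode == "staircase") {
          ssd_ms <- update_ssd(ssd_ms, stop_success = !lifted, params)
        }
      }
    }
    rows[[b]] <- out
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Replay the staircase over a recorded session
#'
#' Internal-consistency oracle: recomputes the SSD sequence that the
#' 1-up/1-down staircase must have produced for a recorded trial list, from
#' the recorded stop successes/failures alone, applying the same reset rules
#' as [run_session()].
#'
#' @param trials a trial data frame (as from [run_session()] or
#'   [read_trials()]) in presentation order, with `trialType`, `signal` and
#'   `response` columns.
#' @param params an [task_parameters()] object.
#' @return Numeric vector, seconds: the predicted SSD for each stop trial,
#'   in order.
#' @export
replay_staircase <- function(trials, params) {
  ssd_ms <- NA_real_
  test_reset_done <- FALSE
  prev_type <- ""
  out <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    type <- trials$trialType[i]
    new_block <- !identical(type, prev_type) || (i > 1 &&
      trials$trial[i] <= trials$trial[i - 1] && type == prev_type &&
      trials$trial[i] == 1)
    if (new_block && identical(type, "practiceMixed") &&
        (i == 1 || prev_type != "practiceMixed")) {
      ssd_ms <- params$initial_ssd
    }
    if (identical(type, "testMixed") && !test_reset_done) {
      ssd_ms <- params$initial_ssd
      test_reset_done <- TRUE
    }
    if (trials$signal[i] == 1) {
      if (is.na(ssd_ms)) ssd_ms <- params$initial_ssd
      out <- c(out, ssd_ms / 1000)
      ssd_ms <- update_ssd(ssd_ms, stop_success = trials$response[i] == 0,
                           params)
    }
    prev_type <- type
  }
  out
}
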