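#' Feedback band labels, from best to worst
#' @keywords internal
feedback_levels <- c("green", "yellow", "orange", "red")

#' Classify go-trial feedback from the response time
#'
#' Converts a go-trial lift time into the colour band shown to the
#' participant.  With the absolute error `e = |rt - target_time| * 1000` ms:
#' `e <= 20` is green, `20 < e <= 40` yellow, `40 < e <= 60` orange and
#' `e > 60` red (default bands; each threshold is inclusive from below).
#' The bands are symmetric about the target: early and late lifts of equal
#' magnitude earn the same colour.
#'
#' @param rt lift time(s) in seconds from fill onset (vectorised); `NA`
#'   values (omissions) yield `NA`.
#' @param params an [task_parameters()] object.
#' @return character vector of band labels among
#'   `"green"`, `"yellow"`, `"orange"`, `"red"`.
#' @examples
#' classify_go_feedback(c(0.800, 0.815, 0.755, 0.870), task_parameters())
#' @export
classify_go_feedback <- function(rt, params) {
  e <- abs(rt - target_time(params)) * 1000
  b <- params$feedback_bands
  ifelse(is.na(e), NA_character_,
    ifelse(e <= b[1], "green",
      ifelse(e <= b[2], "yellow",
        ifelse(e <= b[3], "orange", "red"))))
}

#' Classify a stop trial as a successful or failed stop
#'
#' A stop trial succeeds only if the key is held through the whole trial
#' (until the moment the bar would have reached the top); any lift after fill
#' onset and before trial end -- even before the bar has stopped -- is a
#' failed stop.
#'
#' @param lifted_before_trial_end logical (vectorised): was the key released
#'   at any point before `trial_duration`?
#' @return `"failure"` where lifted, `"success"` otherwise.
#' @export
classify_stop_outcome <- function(lifted_before_trial_end) {
  ifelse(lifted_before_trial_end, "failure", "success")
}

#' Advance the SSD staircase after a stop trial
#'
#' The 1-up/1-down tracking rule: a successful stop makes the next stop
#' harder (SSD increases by `step_size`), a failed stop makes it easier (SSD
#' decreases by `step_size`).  The result is clamped to
#' `[min_ssd, max_ssd]`.  Go trials never touch the staircase.  This rule
#' tracks the SSD at which the participant responds on 50% of stop trials.
#'
#' @param ssd current SSD in ms.
#' @param stop_success logical: was the stop successful?
#' @param params an [task_parameters()] object.
#' @return the new SSD in ms.
#' @examples
#' p <- task_parameters()
#' update_ssd(500, TRUE, p)   # 525
#' update_ssd(500, FALSE, p)  # 475
#' update_ssd(775, TRUE, p)   # clamped at 775
#' @export
update_ssd <- function(ssd, stop_success, params) {
  out <- ssd + ifelse(stop_success, params$step_size, -params$step_size)
  pmin(pmax(out, params$min_ssd), params$max_ssd)
}
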