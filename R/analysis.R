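#' Go-trial descriptives
#'
#' Summarises the go trials of a session: trial and omission counts, mean
#' and SD of the lift times, and the proportion of trials in each feedback
#' band.  An omission is a go trial with no lift before the bar fills
#' (`response == 0`).  Band proportions are computed over all go trials, so
#' together with the omission proportion they sum to one.
#'
#' @param trials trial data frame containing at least one go trial
#'   (`signal == 0`), with `response` and `rt` columns.
#' @param params an [task_parameters()] object (band thresholds and target).
#' @return A one-row data frame: `n_go`, `mean_rt`, `sd_rt`, `n_omissions`,
#'   `prop_green`, `prop_yellow`, `prop_orange`, `prop_red`,
#'   `prop_omission`.
#' @export
compute_go_metrics <- function(trials, params) {
  go <- trials[trials$signal == 0, , drop = FALSE]
  if (!nrow(go)) stop("no go trials to summarise")
  omitted <- go$response == 0 | is.na(go$rt)
  rts <- go$rt[!omitted]
  bands <- classify_go_feedback(rts, params)
  n <- nrow(go)
  counts <- table(factor(bands, levels = feedback_levels))
  data.frame(
    n_go = n,
    mean_rt = if (length(rts)) mean(rts) else NA_real_,
    sd_rt = if (length(rts) > 1) stats::sd(rts) else NA_real_,
    n_omissions = sum(omitted),
    prop_green = counts[["green"]] / n,
    prop_yellow = counts[["yellow"]] / n,
    prop_orange = counts[["orange"]] / n,
    prop_red = counts[["red"]] / n,
    prop_omission = sum(omitted) / n
  )
}

#' Probability of responding given a stop signal
#'
#' The fraction of stop trials on which a response was made (failed stops).
#' Equals the mean of the binary `response` column over stop trials.
#'
#' @param trials trial data frame containing at least one stop trial.
#' @return a probability in `[0, 1]`.
#' @export
p_respond_given_signal <- function(trials) {
  stop_trials <- trials[trials$signal == 1, , drop = FALSE]
  if (!nrow(stop_trials)) stop("no stop trials")
  mean(stop_trials$response == 1)
}

#' Integration-method SSRT estimate (with replacement of omissions)
#'
#' The consensus nonparametric estimator: under the independent horse-race
#' model, the finishing time of the stop process is the point of the go RT
#' distribution that `p(respond|signal)` of go responses beat.  Each go
#' omission is replaced by the trial duration (the slowest possible
#' response), the augmented RTs are sorted ascending, the
#' `ceiling(p_respond * N)`-th value (1-based) is taken as the quantile RT,
#' and the mean SSD is subtracted:
#' `SSRT = quantile_rt - mean_ssd`.
#'
#' @param go_rts numeric vector of observed go lift times, seconds.
#' @param n_go_omissions number of go omissions to append as
#'   `trial_duration`.
#' @param p_respond probability of responding given a stop signal, in
#'   `(0, 1]`.  A value of 0 leaves the quantile undefined; `NA` is
#'   returned with a warning.
#' @param mean_ssd mean stop-signal delay, seconds.
#' @param params an [task_parameters()] object (for the trial duration).
#' @return SSRT in seconds (`NA` if `p_respond == 0`).
#' @export
estimate_ssrt_integration <- function(go_rts, n_go_omissions, p_respond,
                                      mean_ssd, params) {
  if (length(go_rts) == 0 && n_go_omissions == 0) {
    stop("no go RTs to build the distribution from")
  }
  if (is.na(p_respond) || p_respond < 0 || p_respond > 1) {
    stop("p_respond must lie in [0, 1]")
  }
  if (p_respond == 0) {
    warning("p(respond|signal) = 0: the quantile is undefined; returning NA")
    return(NA_real_)
  }
  augmented <- sort(c(go_rts, rep(params$trial_duration, n_go_omissions)))
  idx <- ceiling(p_respond * length(augmented))
  augmented[idx] - mean_ssd
}

#' Empirical inhibition function
#'
#' The probability of responding as a function of the stop-signal delay:
#' stop trials are grouped into SSD bins of width `bin_width` and
#' `p(respond)` is computed per bin.  Empty bins are omitted.
#'
#' @param trials trial data frame containing at least one stop trial with a
#'   defined `ssd`.
#' @param bin_width bin width in seconds (strictly positive).
#' @return A data frame with one row per non-empty bin: `ssd_bin` (bin
#'   midpoint, seconds), `n_trials`, `p_respond`.
#' @export
inhibition_function <- function(trials, bin_width = 0.05) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be strictly positive")
  }
  stop_trials <- trials[trials$signal == 1 & !is.na(trials$ssd), ,
                        drop = FALSE]
  if (!nrow(stop_trials)) stop("no stop trials with a defined SSD")
  bin <- floor(stop_trials$ssd / bin_width)
  agg <- stats::aggregate(
    list(p_respond = stop_trials$response == 1),
    by = list(bin = bin), FUN = mean)
  counts <- as.vector(table(bin)[as.character(agg$bin)])
  out <- data.frame(
    ssd_bin = (agg$bin + 0.5) * bin_width,
    n_trials = counts,
    p_respond = agg$p_respond
  )
  out[order(out$ssd_bin), , drop = FALSE]
}

#' Proactive inhibition
#'
#' Anticipatory slowing induced by the possibility of stop trials: the
#' change in go-trial RT mean and SD between the stop-free test go block and
#' the go trials of the mixed test blocks (mixed minus go-only; positive
#' values mean slowing / added variability under stop-trial context).
#' Omissions are excluded from both sides.
#'
#' @param testgo_trials go trials of the go-only test block.
#' @param mixed_go_trials go trials of the mixed (go + stop) test blocks.
#' @return A one-row data frame: `delta_mean_rt`, `delta_sd_rt` (seconds).
#' @export
proactive_inhibition <- function(testgo_trials, mixed_go_trials) {
  grab <- function(d, what) {
    d <- d[d$signal == 0 & d$response == 1 & !is.na(d$rt), , drop = FALSE]
    if (!nrow(d)) stop("no responded go trials in the ", what, " set")
    d$rt
  }
  a <- grab(testgo_trials, "test-go")
  b <- grab(mixed_go_trials, "mixed-block")
  data.frame(
    delta_mean_rt = mean(b) - mean(a),
    delta_sd_rt = stats::sd(b) - stats::sd(a)
  )
}

# Split a session into the trial sets the analysis operates on.  When the
# file carries block labels, practice blocks are excluded and the go RT
# distribution entering the SSRT estimate is taken from the mixed test
# blocks (the blocks the stop trials live in); without labels (STOP-IT
# dialect) every trial is treated as a mixed test trial.
partition_session <- function(trials) {
  if ("trialType" %in% names(trials)) {
    list(
      mixed = trials[trials$trialType %in% c("testMixed"), , drop = FALSE],
      testgo = trials[trials$trialType == "testGo", , drop = FALSE]
    )
  } else {
    list(mixed = trials, testgo = trials[0, , drop = FALSE])
  }
}

#' Analyse one participant's session
#'
#' The full per-participant summary: go descriptives, stop descriptives,
#' the integration-method SSRT, and (when a go-only test block is present)
#' the proactive-inhibition contrast.  Practice blocks are recorded in the
#' data file but excluded from analysis; files without block labels
#' (STOP-IT dialect) are analysed whole.  The mean SSD and the go RT
#' distribution entering the SSRT estimate both come from the mixed test
#' blocks.
#'
#' @param trials trial data frame from [read_trials()] or [run_session()].
#' @param params an [task_parameters()] object.
#' @param id participant identifier for the output row; defaults to the
#'   `id` column if present.
#' @return A one-row data frame combining [compute_go_metrics()] (over
#'   mixed-block go trials), stop metrics (`n_stop`, `p_respond_signal`,
#'   `mean_ssd`, `mean_signal_respond_rt`, `ssrt`) and
#'   [proactive_inhibition()] deltas (`NA` without a test go block).
#' @export
analyze_participant <- function(trials, params = task_parameters(),
                                id = NULL) {
  if (!nrow(trials)) stop("empty session")
  if (is.null(id)) {
    id <- if ("id" %in% names(trials)) as.character(trials$id[1]) else "unknown"
  }
  parts <- partition_session(trials)
  mixed <- parts$mixed
  if (!nrow(mixed)) stop("no mixed-block trials to analyse")

  go <- compute_go_metrics(mixed, params)
  stop_trials <- mixed[mixed$signal == 1, , drop = FALSE]

  if (nrow(stop_trials)) {
    p_resp <- p_respond_given_signal(mixed)
    mean_ssd <- mean(stop_trials$ssd)
    sr_rts <- stop_trials$rt[stop_trials$response == 1]
    go_resp <- mixed[mixed$signal == 0, , drop = FALSE]
    go_rts <- go_resp$rt[go_resp$response == 1 & !is.na(go_resp$rt)]
    ssrt <- if (p_resp > 0) {
      estimate_ssrt_integration(go_rts, go$n_omissions, p_resp, mean_ssd,
                                params)
    } else NA_real_
    stop_m <- data.frame(
      n_stop = nrow(stop_trials),
      p_respond_signal = p_resp,
      mean_ssd = mean_ssd,
      mean_signal_respond_rt = if (length(sr_rts)) mean(sr_rts) else NA_real_,
      ssrt = ssrt
    )
  } else {
    stop_m <- data.frame(n_stop = 0L, p_respond_signal = NA_real_,
                         mean_ssd = NA_real_,
                         mean_signal_respond_rt = NA_real_, ssrt = NA_real_)
  }

  pro <- if (nrow(parts$testgo)) {
    proactive_inhibition(parts$testgo, mixed)
  } else {
    data.frame(delta_mean_rt = NA_real_, delta_sd_rt = NA_real_)
  }
  cbind(data.frame(id = id, stringsAsFactors = FALSE), go, stop_m, pro)
}

#' Batch-analyse a directory (or list) of data files
#'
#' Reads and analyses every trial file, one output row per participant.  A
#' file that fails to parse or analyse is skipped with a warning naming it;
#' the rest of the batch proceeds.
#'
#' @param input a directory containing `.txt` trial files, or a character
#'   vector of file paths.
#' @param dialect `"OSARI"` or `"STOP-IT"`, passed to [read_trials()].
#' @param params an [task_parameters()] object.
#' @return A data frame with one [analyze_participant()] row per readable
#'   file, plus a `file` column.
#' @export
analyze_batch <- function(input, dialect = c("OSARI", "STOP-IT"),
                          params = task_parameters()) {
  dialect <- match.arg(dialect)
  files <- if (length(input) == 1 && dir.exists(input)) {
    list.files(input, pattern = "\\.txt$", full.names = TRUE)
  } else {
    input
  }
  files <- setdiff(files, files[basename(files) == "manifest.txt"])
  if (!length(files)) stop("no input files")
  rows <- list()
  for (f in files) {
    row <- tryCatch({
      trials <- read_trials(f, dialect = dialect)
      cbind(analyze_participant(trials, params),
            data.frame(file = basename(f), stringsAsFactors = FALSE))
    }, error = function(e) {
      warning("skipping ", basename(f), ": ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) stop("no file could be analysed")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
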