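block_labels <- c("practiceGo", "testGo", "practiceMixed", "testMixed")

#' Specify one block of trials
#'
#' A block is a bag of go and stop trials with a label identifying its role
#' in the session.  The underlying trial sequence (used verbatim in
#' sequential order, permuted in random order) defaults to all go trials
#' followed by all stop trials; [block_from_table()] builds a block whose
#' sequence follows a condition table row-by-row.
#'
#' @param label one of `"practiceGo"`, `"testGo"`, `"practiceMixed"`,
#'   `"testMixed"`.
#' @param n_go,n_stop non-negative trial counts.
#' @param fixed_stop_times optional numeric vector of length `n_stop` (ms):
#'   the SSD of each stop trial when the session runs in fixed-SSD mode, in
#'   sequence order.
#' @param sequence optional integer vector of 0 (go) / 1 (stop) giving the
#'   canonical row order; must contain exactly `n_go` zeros and `n_stop`
#'   ones.  Defaults to all go then all stop.
#' @return An object of class `osari_block`.
#' @export
block_spec <- function(label, n_go, n_stop = 0,
                       fixed_stop_times = NULL, sequence = NULL) {
  label <- match.arg(label, block_labels)
  if (!is.numeric(n_go) || length(n_go) != 1 || n_go < 0 || n_go != round(n_go)) {
    stop("n_go must be a single non-negative integer")
  }
  if (!is.numeric(n_stop) || length(n_stop) != 1 || n_stop < 0 || n_stop != round(n_stop)) {
    stop("n_stop must be a single non-negative integer")
  }
  if (is.null(sequence)) {
    sequence <- c(rep(0L, n_go), rep(1L, n_stop))
  }
  sequence <- as.integer(sequence)
  if (!all(sequence %in% c(0L, 1L)) ||
      sum(sequence == 0L) != n_go || sum(sequence == 1L) != n_stop) {
    stop("sequence must contain exactly n_go zeros and n_stop ones")
  }
  if (!is.null(fixed_stop_times)) {
    if (length(fixed_stop_times) != n_stop) {
      stop("fixed_stop_times must have one entry per stop trial")
    }
  }
  structure(
    list(label = label, n_go = as.integer(n_go), n_stop = as.integer(n_stop),
         fixed_stop_times = fixed_stop_times, sequence = sequence),
    class = "osari_block"
  )
}

#' @export
print.osari_block <- function(x, ...) {
  cat(sprintf("<%s block: %d go + %d stop trials%s>\n", x$label, x$n_go,
              x$n_stop,
              if (is.null(x$fixed_stop_times)) "" else ", fixed SSDs"))
  invisible(x)
}

#' Build a block from a condition table
#'
#' Condition tables are delimited text files with a `trialType` column
#' (`"go"` / `"stop"`) and a `fixedStopTime` column (SSD in ms, used only in
#' fixed-SSD mode; `NA` on go rows).  Row order is the sequence used when
#' trials are presented sequentially.
#'
#' @param table a data frame as returned by [read_condition_table()].
#' @param label block label, as in [block_spec()].
#' @return An `osari_block`.
#' @export
block_from_table <- function(table, label) {
  if (!"trialType" %in% names(table)) {
    stop("condition table must have a 'trialType' column")
  }
  type <- tolower(trimws(as.character(table$trialType)))
  if (!all(type %in% c("go", "stop"))) {
    stop("condition table trialType entries must be 'go' or 'stop'")
  }
  sequence <- as.integer(type == "stop")
  fixed <- NULL
  if ("fixedStopTime" %in% names(table)) {
    fst <- suppressWarnings(as.numeric(table$fixedStopTime))
    fixed <- fst[sequence == 1L]
    if (length(fixed) && anyNA(fixed)) {
      stop("fixedStopTime must be numeric on every stop row")
    }
    if (!length(fixed)) fixed <- NULL
  }
  block_spec(label, n_go = sum(sequence == 0L), n_stop = sum(sequence == 1L),
             fixed_stop_times = fixed, sequence = sequence)
}

#' Read or write a condition table
#'
#' @param path file path; whitespace- or tab-delimited text with a header
#'   row naming at least `trialType` and optionally `fixedStopTime`.
#' @return `read_condition_table()`: a data frame with columns `trialType`
#'   and (if present) `fixedStopTime`.
#' @export
read_condition_table <- function(path) {
  if (!file.exists(path)) stop("condition table not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE)
  if (!"trialType" %in% names(tab)) {
    stop("condition table must have a 'trialType' column: ", path)
  }
  tab
}

#' @rdname read_condition_table
#' @param table data frame with a `trialType` column.
#' @export
write_condition_table <- function(table, path) {
  utils::write.table(table, path, sep = " ", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Assemble the default session
#'
#' The standard session is, in order: a practice go block (10 go trials), a
#' test go block (30 go trials, the baseline for proactive inhibition), a
#' practice mixed block (15 go + 5 stop), and three test mixed blocks of 80
#' trials each (60 go + 20 stop, i.e. 25% stop trials) -- 300 trials in
#' total.  The practice blocks and the test go block can be dropped,
#' mirroring the task's two start-up checkboxes: disabling practice removes
#' both practice blocks; disabling the test go block removes only it.
#'
#' @param params an [task_parameters()] object.
#' @param practice include the practice go and practice mixed blocks?
#' @param test_go include the 30-trial test go block?
#' @param fixed_stop_times optional list with elements `practiceMixed`
#'   (length 5) and `testMixed` (length 20, reused for each test block):
#'   per-stop-trial SSDs in ms for fixed-SSD mode.
#' @return A list of [block_spec()] objects in presentation order.
#' @examples
#' length(default_session(task_parameters()))  # 6 blocks
#' @export
default_session <- function(params, practice = TRUE, test_go = TRUE,
                            fixed_stop_times = NULL) {
  fst_pm <- fixed_stop_times$practiceMixed
  fst_tm <- fixed_stop_times$testMixed
  blocks <- list()
  if (practice) {
    blocks <- c(blocks, list(block_spec("practiceGo", n_go = 10)))
  }
  if (test_go) {
    blocks <- c(blocks, list(block_spec("testGo", n_go = 30)))
  }
  if (practice) {
    blocks <- c(blocks, list(
      block_spec("practiceMixed", n_go = 15, n_stop = 5,
                 fixed_stop_times = fst_pm)))
  }
  for (i in 1:3) {
    blocks <- c(blocks, list(
      block_spec("testMixed", n_go = 60, n_stop = 20,
                 fixed_stop_times = fst_tm)))
  }
  blocks
}

#' Schedule the trials of one block
#'
#' Expands a block specification into an ordered trial list.  In
#' `"sequential"` order the canonical sequence (the condition-table row
#' order) is preserved; in `"random"` order it is permuted with the current
#' RNG state (seed it, or pass `seed`, for reproducibility).  Fixed stop
#' times travel with their stop trial through the permutation.
#'
#' @param spec an [block_spec()] object.
#' @param order `"random"` or `"sequential"`.
#' @param seed optional integer seed used only for this permutation.
#' @return A data frame with columns `trialType` (block label), `trial`
#'   (1-based index within block), `signal` (0 go / 1 stop) and
#'   `planned_ssd` (ms, `NA` except for stop trials of a fixed-SSD block).
#' @export
schedule_block <- function(spec, order = c("random", "sequential"),
                           seed = NULL) {
  order <- match.arg(order)
  n <- spec$n_go + spec$n_stop
  signal <- spec$sequence
  planned <- rep(NA_real_, n)
  if (!is.null(spec$fixed_stop_times)) {
    planned[signal == 1L] <- spec$fixed_stop_times
  }
  if (order == "random" && n > 1) {
    perm <- if (is.null(seed)) {
      sample.int(n)
    } else {
      with_seed(seed, sample.int(n))
    }
    signal <- signal[perm]
    planned <- planned[perm]
  }
  data.frame(
    trialType = rep(spec$label, n),
    trial = seq_len(n),
    signal = signal,
    planned_ssd = planned,
    stringsAsFactors = FALSE
  )
}
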