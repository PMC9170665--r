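trial_file_columns <- c("id", "block", "trialType", "trial", "signal",
                        "response", "ssd", "rt")

# Render a numeric column for the trial file: undefined values become the
# literal "NaN"; finite values use the shortest decimal representation that
# round-trips the double exactly, so write -> read is lossless.
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NaN")
    for (d in c(1:15, 17)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    s
  }, character(1))
}

#' Write a trial-level data file
#'
#' Writes the single-participant `.txt` trial format: a header row and one
#' space-delimited row per trial with columns `id block trialType trial
#' signal response ssd rt`.  Undefined values are rendered literally as
#' `NaN`: `ssd` is `NaN` on go trials and `rt` is `NaN` when no response was
#' made (correct stops and go omissions).  Both `ssd` and `rt` are in
#' seconds.  The STOP-IT dialect is identical except that it omits the
#' `trialType` column.
#'
#' @param trials trial data frame (from [run_session()], [read_trials()] or
#'   equivalent) with columns `block`, `trialType`, `trial`, `signal`,
#'   `response`, `ssd`, `rt` (plus `id` if `id` is not supplied).
#' @param path output file path.
#' @param id participant identifier written into every row; defaults to the
#'   `id` column of `trials`.
#' @param dialect `"OSARI"` (default) or `"STOP-IT"`.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, id = NULL,
                         dialect = c("OSARI", "STOP-IT")) {
  dialect <- match.arg(dialect)
  if (is.null(id)) {
    if (!"id" %in% names(trials)) {
      stop("supply `id` or include an `id` column in `trials`")
    }
    id <- trials$id
  }
  if (any(!nzchar(as.character(id)))) stop("participant id must be non-empty")
  needed <- setdiff(trial_file_columns, c("id", "trialType"))
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    stop("trials is missing column(s): ", paste(missing, collapse = ", "))
  }

  n <- nrow(trials)
  cols <- list(
    id = rep_len(as.character(id), n),
    block = as.integer(trials$block),
    trialType = if (n) as.character(trials$trialType) else character(0),
    trial = as.integer(trials$trial),
    signal = as.integer(trials$signal),
    response = as.integer(trials$response),
    ssd = fmt_num(as.numeric(trials$ssd)),
    rt = fmt_num(as.numeric(trials$rt))
  )
  keep <- trial_file_columns
  if (dialect == "STOP-IT") keep <- setdiff(keep, "trialType")
  lines <- c(paste(keep, collapse = " "),
             if (n) do.call(paste, cols[keep]))
  writeLines(lines, path)
  invisible(path)
}

parse_num_col <- function(x, name) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & x != "NaN" & !is.na(x))
  if (length(bad)) {
    stop("non-numeric '", name, "' value \"", x[bad[1]], "\" at row ", bad[1])
  }
  # the file's NaN marker means "undefined"; represent it as NA internally
  out[is.nan(out)] <- NA_real_
  out
}

#' Read a trial-level data file
#'
#' Parses a `.txt` trial file written by this package or by the task itself.
#' Space- and tab-delimited files are both accepted.  The OSARI dialect
#' requires the `trialType` column; the STOP-IT dialect tolerates its
#' absence (the two formats are otherwise identical).  Malformed `signal`
#' or `response` codes and non-numeric `ssd`/`rt` entries are rejected with
#' their row number.
#'
#' @param path input file path.
#' @param dialect `"OSARI"` (default) or `"STOP-IT"`.
#' @return A data frame with columns `id` (character), `block`, `trial`,
#'   `signal`, `response` (integer), `ssd`, `rt` (numeric seconds, `NA`
#'   where the file says `NaN`) and, when present, `trialType` (character).
#' @export
read_trials <- function(path, dialect = c("OSARI", "STOP-IT")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  required <- setdiff(trial_file_columns, "trialType")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
  if (dialect == "OSARI" && !"trialType" %in% names(raw)) {
    stop("missing 'trialType' column in ", path,
         " (use dialect = \"STOP-IT\" for files without it)")
  }

  sig <- suppressWarnings(as.integer(raw$signal))
  bad <- which(is.na(sig) | !(sig %in% c(0L, 1L)))
  if (length(bad)) {
    stop("invalid 'signal' value \"", raw$signal[bad[1]], "\" at row ", bad[1])
  }
  resp <- suppressWarnings(as.integer(raw$response))
  bad <- which(is.na(resp) | !(resp %in% c(0L, 1L)))
  if (length(bad)) {
    stop("invalid 'response' value \"", raw$response[bad[1]], "\" at row ",
         bad[1])
  }

  out <- data.frame(
    id = raw$id,
    block = suppressWarnings(as.integer(raw$block)),
    trial = suppressWarnings(as.integer(raw$trial)),
    signal = sig,
    response = resp,
    ssd = parse_num_col(raw$ssd, "ssd"),
    rt = parse_num_col(raw$rt, "rt"),
    stringsAsFactors = FALSE
  )
  if ("trialType" %in% names(raw)) {
    out$trialType <- raw$trialType
    out <- out[, c("id", "block", "trialType", "trial", "signal",
                   "response", "ssd", "rt")]
  }
  out
}

#' Build the standard data-file name
#'
#' Data files are named `ID_OSARI_yyyy_mo_d_hhmm`: participant id, year,
#' English month name, unpadded day, and hour-minute.  The timestamp makes
#' repeated sessions with the same participant id distinct.
#'
#' @param id non-empty participant identifier.
#' @param timestamp a `POSIXct`/`POSIXlt` time (defaults to now).
#' @return the file name stem (no extension).
#' @examples
#' build_filename("s01", as.POSIXct("2021-11-09 14:05:00"))
#' # "s01_OSARI_2021_November_9_1405"
#' @export
build_filename <- function(id, timestamp = Sys.time()) {
  if (length(id) != 1 || is.na(id) || !nzchar(as.character(id))) {
    stop("participant id must be a single non-empty string")
  }
  lt <- as.POSIXlt(timestamp)
  paste(as.character(id), "OSARI",
        format(lt, "%Y"),
        month.name[lt$mon + 1],   # English month name, locale-independent
        lt$mday,                  # day without zero padding
        format(lt, "%H%M"),
        sep = "_")
}
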