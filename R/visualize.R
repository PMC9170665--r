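#' Plot-data bundle for one participant
#'
#' Computes the six per-participant summary tables behind the standard
#' six-panel session figure: (a) go descriptives, (b) RT by trial with a
#' correctness flag, (c) RT densities of correct go and failed-stop
#' responses, (d) stop descriptives, (e) SSD by trial, and (f) the
#' inhibition function.  Rendering to an image (see [plot_panels()]) is a
#' thin optional layer over these tables; sessions without stop trials get
#' empty stop-side tables.
#'
#' @param trials trial data frame from [read_trials()] or [run_session()].
#' @param params an [task_parameters()] object.
#' @param bin_width inhibition-function bin width, seconds.
#' @return An object of class `osari_panels`: a named list of data frames
#'   `go_descriptives`, `rt_by_trial`, `rt_density`, `stop_descriptives`,
#'   `ssd_by_trial`, `inhibition_function`.  `rt_by_trial` carries the
#'   session-wide trial sequence, the block index and `correct` (go trial
#'   responded / stop trial held).
#' @export
visualize_participant <- function(trials, params = task_parameters(),
                                  bin_width = 0.05) {
  if (!nrow(trials)) stop("empty session")
  seq_idx <- seq_len(nrow(trials))
  correct <- (trials$signal == 0 & trials$response == 1) |
    (trials$signal == 1 & trials$response == 0)
  rt_by_trial <- data.frame(
    trial_seq = seq_idx,
    block = trials$block,
    trialType = if ("trialType" %in% names(trials)) trials$trialType else NA,
    signal = trials$signal,
    rt = trials$rt,
    correct = correct
  )

  dens_tab <- function(rts, type) {
    rts <- rts[!is.na(rts)]
    if (length(rts) < 2) {
      return(data.frame(type = character(0), rt = numeric(0),
                        density = numeric(0)))
    }
    d <- stats::density(rts)
    data.frame(type = type, rt = d$x, density = d$y)
  }
  go_rts <- trials$rt[trials$signal == 0 & trials$response == 1]
  sr_rts <- trials$rt[trials$signal == 1 & trials$response == 1]
  rt_density <- rbind(dens_tab(go_rts, "go"),
                      dens_tab(sr_rts, "signal-respond"))

  has_stop <- any(trials$signal == 1)
  stop_rows <- which(trials$signal == 1)
  ssd_by_trial <- data.frame(
    trial_seq = seq_idx[stop_rows],
    block = trials$block[stop_rows],
    ssd = trials$ssd[stop_rows],
    responded = trials$response[stop_rows] == 1
  )

  structure(
    list(
      go_descriptives = compute_go_metrics(trials, params),
      rt_by_trial = rt_by_trial,
      rt_density = rt_density,
      stop_descriptives = if (has_stop) {
        sr <- trials$rt[trials$signal == 1 & trials$response == 1]
        data.frame(
          n_stop = sum(trials$signal == 1),
          p_respond_signal = p_respond_given_signal(trials),
          mean_ssd = mean(trials$ssd[stop_rows]),
          mean_signal_respond_rt = if (length(sr)) mean(sr) else NA_real_
        )
      } else {
        data.frame(n_stop = integer(0), p_respond_signal = numeric(0),
                   mean_ssd = numeric(0), mean_signal_respond_rt = numeric(0))
      },
      ssd_by_trial = ssd_by_trial,
      inhibition_function = if (has_stop) {
        inhibition_function(trials, bin_width)
      } else {
        data.frame(ssd_bin = numeric(0), n_trials = integer(0),
                   p_respond = numeric(0))
      }
    ),
    class = "osari_panels"
  )
}

#' @export
print.osari_panels <- function(x, ...) {
  cat("Six-panel session summary:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %d row(s)\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write a plot-data bundle to delimited text files
#'
#' @param panels an `osari_panels` object.
#' @param dir output directory (created if needed); one
#'   `<prefix>_<panel>.txt` file per table.
#' @param prefix file-name prefix, typically the participant id.
#' @return the written paths, invisibly.
#' @export
write_panels <- function(panels, dir, prefix = "participant") {
  stopifnot(inherits(panels, "osari_panels"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(panels)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".txt"))
    utils::write.table(panels[[nm]], p, sep = " ", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Render the six-panel figure
#'
#' Optional graphical layer over [visualize_participant()]; requires
#' ggplot2.  Returns the panels as a named list of ggplot objects (empty
#' panels are dropped) for the caller to arrange or save.
#'
#' @param panels an `osari_panels` object.
#' @return named list of ggplot objects.
#' @export
plot_panels <- function(panels) {
  stopifnot(inherits(panels, "osari_panels"))
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_panels() requires the ggplot2 package")
  }
  gg <- ggplot2::ggplot
  aes <- ggplot2::aes
  out <- list()
  rbt <- panels$rt_by_trial
  out$rt_by_trial <- gg(rbt[!is.na(rbt$rt), ],
                        aes(x = trial_seq, y = rt,
                            shape = factor(signal),
                            colour = correct)) +
    ggplot2::geom_point() +
    ggplot2::scale_shape_manual(values = c(`0` = 15, `1` = 16),
                                labels = c("go", "stop")) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "blue", `FALSE` = "red")) +
    ggplot2::labs(x = "Trial", y = "RT (s)")
  if (nrow(panels$rt_density)) {
    out$rt_density <- gg(panels$rt_density,
                         aes(x = rt, y = density,
                             colour = type)) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "RT (s)", y = "Density")
  }
  if (nrow(panels$ssd_by_trial)) {
    out$ssd_by_trial <- gg(panels$ssd_by_trial,
                           aes(x = trial_seq, y = ssd,
                               colour = !responded)) +
      ggplot2::geom_point() +
      ggplot2::scale_colour_manual(values = c(`TRUE` = "blue",
                                              `FALSE` = "red")) +
      ggplot2::labs(x = "Trial", y = "SSD (s)")
  }
  if (nrow(panels$inhibition_function)) {
    out$inhibition_function <- gg(panels$inhibition_function,
                                  aes(x = ssd_bin,
                                      y = p_respond)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "SSD (s)", y = "P(respond | signal)")
  }
  out
}
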