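go_df <- function(rts, responded = rep(TRUE, length(rts)),
                  type = "testMixed") {
  data.frame(block = 1L, trialType = type, trial = seq_along(rts),
             signal = 0L, response = as.integer(responded),
             ssd = NA_real_, rt = ifelse(responded, rts, NA_real_))
}

stop_df <- function(ssd, responded, rt = NA_real_, type = "testMixed") {
  data.frame(block = 1L, trialType = type, trial = seq_along(ssd),
             signal = 1L, response = as.integer(responded),
             ssd = ssd, rt = ifelse(responded, rt, NA_real_))
}

test_that("go metrics match hand computation", {
  p <- task_parameters()
  m <- compute_go_metrics(go_df(c(0.79, 0.80, 0.81)), p)
  expect_equal(m$n_go, 3)
  expect_equal(m$mean_rt, 0.80)
  expect_equal(m$sd_rt, 0.01)
  expect_equal(m$n_omissions, 0)
  expect_equal(m$prop_green, 1)
  expect_equal(m$prop_omission, 0)

  # one red among greens shifts the proportions
  m2 <- compute_go_metrics(go_df(c(0.79, 0.80, 0.81, 0.87)), p)
  expect_equal(m2$prop_green, 0.75)
  expect_equal(m2$prop_red, 0.25)

  # all omissions: mean undefined, proportions still close
  m3 <- compute_go_metrics(go_df(c(0.8, 0.8), responded = c(FALSE, FALSE)), p)
  expect_true(is.na(m3$mean_rt))
  expect_equal(m3$n_omissions, 2)
  expect_equal(m3$prop_omission, 1)

  expect_error(compute_go_metrics(stop_df(0.5, TRUE, 0.7), p), "no go")
})

test_that("band, omission and response proportions always sum to one", {
  p <- task_parameters()
  set.seed(14)
  for (i in 1:20) {
    n <- sample(1:40, 1)
    responded <- runif(n) < 0.9
    m <- compute_go_metrics(go_df(runif(n, 0.6, 1.0), responded), p)
    total <- m$prop_green + m$prop_yellow + m$prop_orange + m$prop_red +
      m$prop_omission
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("p(respond|signal) is the failed-stop fraction", {
  expect_equal(p_respond_given_signal(stop_df(rep(0.5, 10),
                                              rep(c(TRUE, FALSE), 5),
                                              rt = 0.7)), 0.5)
  expect_equal(p_respond_given_signal(stop_df(rep(0.5, 4), rep(FALSE, 4))), 0)
  trials <- stop_df(rep(0.5, 20), c(rep(TRUE, 13), rep(FALSE, 7)), rt = 0.7)
  expect_equal(p_respond_given_signal(trials), 0.65)
  # definitional cross-check: it is the mean of the binary response column
  expect_equal(p_respond_given_signal(trials),
               mean(trials$response[trials$signal == 1]))
  expect_error(p_respond_given_signal(go_df(0.8)), "no stop")
})

test_that("integration-method SSRT reproduces the worked examples", {
  p <- task_parameters()
  rts <- seq(0.61, 0.70, by = 0.01)
  expect_equal(estimate_ssrt_integration(rts, 0, 0.5, 0.50, p), 0.15)
  # two omissions are replaced by the 1 s trial duration: index 6 of 12
  expect_equal(estimate_ssrt_integration(rts, 2, 0.5, 0.50, p), 0.16)
  # degenerate quantile at p = 1: the maximum RT
  expect_equal(estimate_ssrt_integration(rts, 0, 1.0, 0.50, p), 0.20)
  expect_warning(out <- estimate_ssrt_integration(rts, 0, 0, 0.5, p),
                 "undefined")
  expect_true(is.na(out))
  expect_error(estimate_ssrt_integration(numeric(0), 0, 0.5, 0.5, p), "no go")
  expect_error(estimate_ssrt_integration(rts, 0, 1.2, 0.5, p), "0, 1")
})

test_that("the estimator matches the brute-force sort-and-walk oracle", {
  p <- task_parameters()
  set.seed(99)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    rts <- round(runif(n, 0.3, 1.0), 3)
    n_om <- sample(0:5, 1)
    p_resp <- sample(seq(0.05, 1, by = 0.05), 1)
    mssd <- round(runif(1, 0.05, 0.775), 3)
    expect_identical(
      estimate_ssrt_integration(rts, n_om, p_resp, mssd, p),
      ssrt_oracle(rts, n_om, p_resp, mssd, p$trial_duration))
  }
})

test_that("the inhibition function bins stop trials consistently", {
  trials <- stop_df(rep(0.5, 8), rep(c(TRUE, FALSE), 4), rt = 0.7)
  one <- inhibition_function(trials, 0.05)
  expect_equal(nrow(one), 1)
  expect_equal(one$p_respond, 0.5)
  expect_equal(one$n_trials, 8)

  # a bin spanning every SSD aggregates to the overall p(respond|signal)
  mixed <- stop_df(c(0.4, 0.4, 0.6, 0.6, 0.7), c(F, F, T, F, T), rt = 0.7)
  wide <- inhibition_function(mixed, bin_width = 2)
  expect_equal(nrow(wide), 1)
  expect_equal(wide$p_respond, p_respond_given_signal(mixed))

  narrow <- inhibition_function(mixed, bin_width = 0.05)
  expect_equal(nrow(narrow), 3)
  expect_equal(sum(narrow$n_trials), 5)

  expect_error(inhibition_function(mixed, 0), "positive")
  expect_error(inhibition_function(go_df(0.8), 0.05), "no stop")
})

test_that("proactive inhibition is the mixed-minus-baseline contrast", {
  base <- go_df(c(0.78, 0.79, 0.80), type = "testGo")
  mixed <- go_df(c(0.80, 0.81, 0.82), type = "testMixed")
  pro <- proactive_inhibition(base, mixed)
  expect_equal(pro$delta_mean_rt, 0.02)
  expect_equal(pro$delta_sd_rt, 0)

  same <- proactive_inhibition(base, base)
  expect_equal(same$delta_mean_rt, 0)
  expect_equal(same$delta_sd_rt, 0)

  expect_error(proactive_inhibition(base[0, ], mixed), "test-go")
})

test_that("participant-level analysis excludes practice and uses mixed-block context", {
  p <- task_parameters()
  trials <- simulate_session(participant_params(), p, seed = 71, id = "s1")
  row <- analyze_participant(trials, p)
  expect_equal(row$id, "s1")
  expect_equal(row$n_go, 180)          # mixed test blocks only
  expect_equal(row$n_stop, 60)
  # mean SSD over test-block stop trials only
  tm <- trials[trials$trialType == "testMixed" & trials$signal == 1, ]
  expect_equal(row$mean_ssd, mean(tm$ssd))
  expect_equal(row$p_respond_signal, mean(tm$response))
  expect_false(is.na(row$ssrt))
  expect_false(is.na(row$delta_mean_rt))

  # without the test go block the proactive contrast is undefined
  no_base <- trials[trials$trialType != "testGo", ]
  row2 <- analyze_participant(no_base, p)
  expect_true(is.na(row2$delta_mean_rt))
})

test_that("STOP-IT and OSARI twins of the same rows yield identical metrics", {
  p <- task_parameters()
  trials <- simulate_session(
    participant_params(), p,
    session = list(block_spec("testMixed", n_go = 60, n_stop = 20)),
    seed = 72, id = "tw")
  osari_path <- withr::local_tempfile(fileext = ".txt")
  stopit_path <- withr::local_tempfile(fileext = ".txt")
  write_trials(trials, osari_path, id = "tw")
  write_trials(trials, stopit_path, id = "tw", dialect = "STOP-IT")
  a <- analyze_participant(read_trials(osari_path), p)
  b <- analyze_participant(read_trials(stopit_path, dialect = "STOP-IT"), p)
  for (col in c("n_go", "mean_rt", "sd_rt", "n_stop", "p_respond_signal",
                "mean_ssd", "mean_signal_respond_rt", "ssrt")) {
    expect_equal(a[[col]], b[[col]], label = col)
  }
})

test_that("the six-panel bundle mirrors the session structure", {
  p <- task_parameters()
  trials <- simulate_session(participant_params(), p, seed = 73, id = "v1")
  panels <- visualize_participant(trials, p)
  expect_s3_class(panels, "osari_panels")
  expect_named(panels, c("go_descriptives", "rt_by_trial", "rt_density",
                         "stop_descriptives", "ssd_by_trial",
                         "inhibition_function"))
  expect_equal(nrow(panels$rt_by_trial), nrow(trials))
  expect_equal(nrow(panels$ssd_by_trial), sum(trials$signal == 1))
  expect_true(all(vapply(panels, nrow, integer(1)) > 0))
  # block bookkeeping carries through
  expect_equal(panels$rt_by_trial$block, trials$block)

  # no stop trials: stop-side panels are empty, go-side populated
  go_only <- run_session(list(block_spec("testGo", n_go = 12)),
                         race_responder(participant_params(), p), p,
                         seed = 74)
  panels2 <- visualize_participant(go_only, p)
  expect_equal(nrow(panels2$stop_descriptives), 0)
  expect_equal(nrow(panels2$ssd_by_trial), 0)
  expect_equal(nrow(panels2$inhibition_function), 0)
  expect_gt(nrow(panels2$rt_by_trial), 0)

  expect_error(visualize_participant(trials[0, ], p), "empty")
})

test_that("batch analysis continues past unreadable files, naming them", {
  dir <- withr::local_tempdir()
  simulate_cohort(2, master_seed = 75,
                  session = list(block_spec("testMixed", n_go = 30,
                                            n_stop = 10)),
                  out_dir = dir)
  writeLines("this is not a trial file", file.path(dir, "corrupt.txt"))
  expect_warning(metrics <- analyze_batch(dir), "corrupt.txt")
  expect_equal(nrow(metrics), 2)
  expect_true(all(is.finite(metrics$ssrt)))
})
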