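# osarir

A headless R implementation of the logic of the OSARI anticipated response
inhibition (ARI) task, together with an independent horse-race participant
simulator and a batch analysis suite for OSARI / STOP-IT trial-level data.

## The problem

Stop-signal tasks measure the ability to cancel a prepared action. In the
ARI variant, the go response is not a reaction to an unpredictable stimulus
but a *planned* key release timed to stop a vertically filling bar at a
target: the bar fills over 1 s and the target sits at 80% of its height, so
the planned lift falls at 800 ms. On stop trials the bar halts early — at
the stop-signal delay (SSD) — and the participant must keep the key held
through the end of the trial.

Performance is interpreted through the independent horse-race model: each
stop trial is a race between a go process (finishing time `T_go`, the
planned lift) and a stop process launched at the SSD (finishing time
`SSRT`, the stop-signal reaction time). The response escapes inhibition iff

```
T_go < SSD + SSRT
```

The covert SSRT is estimated nonparametrically by the integration method
with replacement: with `p = P(respond | signal)` and go RTs augmented by
one trial-duration value per go omission,

```
SSRT = Q_p(go RT) − mean SSD,    Q_p = ceiling(p · N)-th sorted RT
```

The task tracks the SSD at which `p = 0.5` with a 1-up/1-down staircase:
after a successful stop the SSD increases by 25 ms, after a failed stop it
decreases by 25 ms, clamped to [50, 775] ms from a 500 ms start.

This package is for researchers who want to (a) reason about and test the
task's scheduling, staircase, feedback and file-format logic without a
graphics stack, (b) generate realistic synthetic cohorts with known
generative parameters for estimator-validation studies, and (c)
batch-analyse real or simulated `.txt` data files (go/stop descriptives,
inhibition function, integration-method SSRT, proactive inhibition).

## Worked example

```r
library(osarir)

params <- task_parameters()        # the standard task configuration
params
#> Anticipated response inhibition task parameters
#>   trial duration : 1 s (bar 3 x 15 cm)
#>   target         : 80% of bar height (t = 0.8 s)
#>   feedback bands : 20/40/60 ms
#>   SSD            : staircase, start 500 ms, step 25 ms, clamps [50, 775] ms

participant <- participant_params(go_mean = 0.80, go_sd = 0.05,
                                  ssrt_mean = 0.20, ssrt_sd = 0.03)
trials <- simulate_session(participant, params, seed = 42, id = "s01")
metrics <- analyze_participant(trials, params)
t(round(metrics[, -1], 3))
#> n_go                   180.000
#> mean_rt                  0.795
#> sd_rt                    0.053
#> n_omissions              0.000
#> prop_green               0.278
#> prop_yellow              0.239
#> prop_orange              0.217
#> prop_red                 0.267
#> prop_omission            0.000
#> n_stop                  60.000
#> p_respond_signal         0.467
#> mean_ssd                 0.587
#> mean_signal_respond_rt   0.767
#> ssrt                     0.199
#> delta_mean_rt           -0.016
#> delta_sd_rt              0.013
```

Reading the output: over the three mixed test blocks (180 go, 60 stop
trials) the simulated participant lifted on average at 0.795 s (target
0.8 s) and responded on 46.7% of stop trials — the staircase held it near
the 50% design aim, with the mean SSD converged at 0.587 s. Failed-stop
responses (0.767 s) are faster than go responses, as the race model
predicts. The integration-method SSRT of 0.199 s recovers the generative
SSRT mean of 0.200 s. The proactive-inhibition deltas compare go RTs in the
mixed blocks against the stop-free test go block.

The same pipeline runs from the shell:

```sh
exec/osari simulate --n 3 --seed 1 --out data/
exec/osari analyze  --in data/ --out results/            # metrics.txt
exec/osari visualize --in data/ --out figures/           # six-panel tables
exec/osari make-config --out config.yaml                 # editable defaults
```

`read_trials()` / `write_trials()` handle the task's `.txt` schema
bit-exactly (literal `NaN` markers: `ssd` on go trials, `rt` on trials with
no response) and accept the STOP-IT dialect, which differs only by lacking
the `trialType` column.

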