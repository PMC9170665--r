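---
title: "Task model, race-model simulation and SSRT estimation in osarir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task model, race-model simulation and SSRT estimation in osarir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osarir)
```

## The task model

An anticipated response inhibition (ARI) trial is built around a vertically
filling bar: the participant presses and holds a key, a uniformly drawn
start interval elapses, and the bar then fills linearly over the trial
duration (1 s by default). On **go trials** the aim is to release the key
when the bar reaches a target at 80% of bar height — i.e. at
`trial_duration * target_fraction` = 800 ms. On **stop trials** the bar
halts at the stop-signal delay (SSD) and the key must stay held through the
full trial duration; any lift before trial end, even one made before the
bar stops, is a failed stop, because the `response` column admits only a
go response (1) or a withheld response (0).

`run_session()` implements this logic headlessly. Rendering arithmetic is
exposed as pure functions: `bar_position(elapsed, params)` is the
time-approach formula `bar_height * elapsed / trial_duration` (5.055 cm at
0.337 s under defaults) and `distance_per_frame(rate, params)` the
space-approach per-refresh increment (0.25 cm at 60 Hz). Both are exact
closed forms and are covered by exact tests.

### Feedback classification

Go feedback depends on the absolute error `e = |rt − 0.8| * 1000` ms:
green for `e ≤ 20`, yellow for `20 < e ≤ 40`, orange for `40 < e ≤ 60`,
red beyond. Each threshold is read inclusively from below ("within 20 ms"
includes 20 ms); this must be pinned for exact tests and is symmetric about
the target by construction. Band order runs green < yellow < orange < red
in increasing severity.

Two edge behaviours are worth making explicit because the task description
leaves them open:

* a lift during the **start interval** aborts and restarts the trial; the
  restart is counted (`early_lift_restarts`) but never consumes a trial
  index;
* a lift within the first 100 ms of the fill (`early_lift_window`) is kept
  as a normal scored response and merely flagged (`encouragement`), since
  only the start-interval lift is described as restarting.

### The staircase

The SSD staircase is the classic 1-up/1-down tracker: +25 ms after a
successful stop, −25 ms after a failed one, clamped to [50, 775] ms,
starting at 500 ms. It converges on the SSD where the probability of
responding is 0.5. The clamps keep the stop signal inside the informative
part of the trial (after 775 ms the planned action has effectively
occurred; below 50 ms almost no bar is shown). The staircase initialises at
the practice mixed block, re-initialises at the first test mixed block, and
then carries across the remaining test blocks — practice performance never
contaminates test SSDs. Step arithmetic is plain addition with clamping;
the step size need not divide the distance to the clamps (remainders are
absorbed by the clamp, so a 50 ms step saturates at 775 via a final 25 ms
move).

In fixed-SSD mode each stop trial instead takes its delay from the
`fixedStopTime` column of a condition table, which is also the mechanism
for sequential (predefined-order) trial presentation. The shipped
condition tables (`inst/extdata/`) reproduce the default 15+5 and 60+20
block compositions; their stop times spread over 200–700 ms to cover the
inhibition function, a package default since no canonical values exist.

### Randomness contract

A session consumes one seeded RNG stream in a documented order — per
block, the trial permutation; per trial, the start-interval draw, then any
draws the responder makes. `run_session(..., seed =)` runs under a local
stream and restores the caller's RNG state, so sessions are bit-reproducible
and composable.

## The race-model simulator

The simulator realises the independent horse-race account. Each trial
draws a go finishing time `T_go ~ N(go_mean, go_sd)` truncated to positive
values; on stop trials a stop finishing time `T_stop ~ N(ssrt_mean,
ssrt_sd)` (same truncation) races it, and the response is made iff
`T_go ≤ SSD + T_stop`, the go process winning exact ties (a measure-zero
event under continuous distributions, but it must be fixed for
integer-millisecond test vectors). Draws beyond the trial duration are
omissions. Optional imperfections are first-class parameters: trigger
failures (the stop process is never launched, probability
`p_trigger_failure`) and start-interval lifts (geometric number of aborted
starts per trial).

Default generative parameters — go ~ N(0.80, 0.05) s, SSRT ~ N(0.20,
0.03) s, no trigger failures — describe a typical adult performing the
task near the target; no empirical go-RT spread is published for this
task, so the value is a plausibility choice made once.

Design choices and what they imply for the tests:

* **Truncated Normal** finishing times are the simplest family whose mean
  is the recovery target; real RT distributions are right-skewed
  (ex-Gaussian), so passing recovery tests here demonstrates estimator
  correctness under the model's own assumptions, not robustness to skew.
* **Context independence holds by construction**: the go distribution is
  identical on go and stop trials, as the integration estimator assumes.
  Violations of this assumption — documented in real ARI data — are out of
  scope, so simulation-based checks say nothing about estimator bias under
  violation.
* Consequently the suite's staircase-convergence, monotone
  inhibition-function and signal-respond-faster-than-go properties are
  checks of internal consistency with race-model theory, not of fidelity
  to any human dataset.

## Analysis

`analyze_participant()` reproduces the standard per-participant summary.
Practice blocks are recorded but excluded; the go-RT distribution entering
the SSRT estimate and the mean SSD both come from the mixed test blocks
(the blocks the stop trials live in). Files without block labels (the
STOP-IT dialect) are analysed whole, which keeps metrics identical between
an OSARI file and its label-stripped twin.

The SSRT estimator is the consensus **integration method with
replacement**: each go omission is replaced by the trial duration, the
augmented RTs are sorted, the `ceiling(p · N)`-th value (1-based) is the
`p = P(respond|signal)` quantile, and the mean SSD is subtracted. The
quantile convention matters at small `N` and across software, so it is
pinned and documented rather than asserted to equal any other
implementation's choice; an independent sort-and-walk oracle checks it
exactly on randomized inputs in the test suite. `p = 0` leaves the
quantile undefined and returns `NA` with a warning rather than a number.

Go omissions in this task are trials with no lift before the bar fills —
rare for a participant aiming at 800 ms, but handled throughout.
`proactive_inhibition()` is the mixed-minus-baseline contrast of go-RT
mean and SD against the stop-free test go block; it is reported as `NA`
when that block was skipped. The module reports descriptives and
estimates only — no inferential machinery.

`visualize_participant()` emits the six panel tables (go descriptives, RT
by trial with correctness, RT densities, stop descriptives, SSD by trial,
inhibition function) as plain data frames; rendering (`plot_panels()`,
ggplot2) is a thin optional layer, so every figure is testable as data.

## Numerical choices

* Trial files store `ssd` and `rt` in **seconds** (the `rt` column is
  defined in seconds; the SSD column mirrors it for symmetry, even though
  delays are discussed in ms elsewhere). Undefined entries are the literal
  string `NaN`: `ssd` on go trials, `rt` whenever no response was made.
* Numbers are written as the shortest decimal string that round-trips the
  IEEE double, so `write_trials()` then `read_trials()` is lossless and
  files remain human-readable.
* The inhibition function bins SSDs by `floor(ssd / bin_width)` and drops
  empty bins; bin midpoints are reported. A bin width spanning the whole
  SSD range therefore reproduces the overall `P(respond|signal)` exactly.
* SSD arithmetic is pure addition/clamping in ms; every recorded SSD lies
  on the grid reachable from the initial value (a property test asserts
  membership).

## Problem sizes used in the checks

The suite validates the staircase design aim by simulating the stationary
default participant through 200 staircased stop trials per seed, averaged
over 20 seeds, and requires the mean response rate to fall in [0.45,
0.55]. Because go trials never touch the staircase, these runs use a
stop-trial-only mixed block — exactly equivalent for staircase behaviour
and considerably faster. SSRT recovery uses 20 replicates of a 600-go /
200-stop session and requires mean bias within ±20 ms; oracle equivalence
is checked on 1000 randomized small inputs. These sizes give stable Monte
Carlo estimates (binomial SE of the pooled response rate ≈ 0.8 percentage
points) while keeping the whole suite in the tens of seconds.

## Known limitations

* Forward simulation only: the package estimates SSRT nonparametrically
  but does not fit the race model (no parametric/Bayesian estimation).
* No modelling of context-independence violations, strategic slowing, or
  ex-Gaussian RT tails; recovery results transfer to real data only to the
  extent the race model's assumptions hold there.
* The graphical task itself (rendering, keyboard timing, photodiode
  validation) is out of scope; the rendering formulas are provided for
  reasoning about stimulus geometry, not for driving a display.
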