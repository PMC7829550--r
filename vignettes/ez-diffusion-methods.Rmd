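---
title: "EZ-diffusion decomposition of attentional task performance: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EZ-diffusion decomposition of attentional task performance: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ezdiffusion)
```

## The model

Two-choice reaction times confound how fast a person processes information
with how cautious they are and with how long stimulus encoding and motor
execution take. The EZ-diffusion model separates these by assuming each
trial is a noisy evidence-accumulation process: evidence starts midway
between two absorbing boundaries a distance $a$ apart, drifts at rate $v$
with within-trial Gaussian noise of scale $s$, and the response is emitted
when a boundary is hit, after which a non-decision time $T_{er}$
(encoding + motor) is added. The observed mean RT therefore splits as
$MRT = MDT + T_{er}$, with $MDT$ the mean first-passage (decision) time.

With $y = -va/s^2$, the unbiased process has closed-form summary moments

$$P_c = \frac{1}{1+e^{y}}, \qquad
  MDT = \frac{a}{2v}\,\frac{1-e^{y}}{1+e^{y}}, \qquad
  VRT = \frac{a s^2}{2 v^3}\,\frac{2 y e^{y} - e^{2y} + 1}{(1+e^{y})^2},$$

and — the point of the EZ approach — the map is invertible: from a cell's
proportion correct, mean of correct RTs and variance of correct RTs, the
three parameters follow in closed form with $L = \mathrm{logit}(P_c)$:

$$v = \mathrm{sign}(P_c - \tfrac12)\, s
      \left[\frac{L\,(P_c^2 L - P_c L + P_c - \tfrac12)}{VRT}\right]^{1/4},
  \qquad a = \frac{s^2 L}{v},$$

with $MDT$ from the forward map and $T_{er} = MRT - MDT$. `ez_forward()` and
`ez_inverse()` implement the two directions; `ez_fit()` applies the
inversion across a table of subject-by-condition cells and returns a
classed model object. The round trip is algebraically exact; the test suite
verifies it to below $10^{-9}$ over $v \in [0.05, 0.6]$,
$a \in [0.05, 0.25]$, $T_{er} \in [0.1, 0.6]$.

### Assumptions and their consequences

The EZ inversion assumes an unbiased start point ($z = a/2$), no
across-trial parameter variability, and that errors are ignorable beyond
their count. It uses only three moments, so it is exactly identified: any
(valid) summary triple maps to parameters, and misfit shows up not as a
residual but in the observed-versus-expected check described below.

### Numerical choices

* **Scaling.** $s = 0.1$, the conventional dimensional constant; it is
  configurable everywhere (`s` argument). Only $v/s$, $a/s$ are identified,
  so rescaling $s, v, a$ together changes nothing (tested).
* **Units.** Internally seconds, so $v$ and $a$ land in the familiar
  0.1–0.6 range; reported tables convert $T_{er}$ and $MDT$ to ms.
* **Edges.** The inversion is undefined at $P_c \in \{0, \tfrac12, 1\}$.
  Observed cells at those values are nudged inward by half a trial
  ($1 \mapsto 1 - 1/2n$, etc.) using the cell's own $n$ — `edge_correct()` —
  and flagged. This is the standard correction for moment-based estimators;
  it mildly shrinks extreme drifts, which is visible (and acceptable) at
  44-trial cells.
* **Negative $T_{er}$.** Retained and flagged, never clipped: clipping
  would bias group means upward exactly where estimates are noisiest.
* **Zero RT variance.** A cell with identical correct RTs (or fewer than
  `min_correct = 5` correct trials) cannot be inverted and is flagged
  `unfit`; it stays in the output with `NA` parameters.

## The simulator

`simulate_condition()` draws first-passage trials from the same Wiener
process, via Euler–Maruyama increments $v\,dt + s\sqrt{dt}\,\varepsilon$
in compiled code. Plain Euler observes the path only at grid points, so it
misses within-step boundary crossings and inflates passage times and
accuracy by $O(\sqrt{dt})$ — about $+0.008$ in $P_c$ at $dt = 10^{-3}$ s
for $v=0.2, a=0.1$. Two remedies are provided: a finer step
($dt = 10^{-4}$ s keeps all three moments within the tolerances used by
the oracle checks), and the `exact_small_step` method, which after each
non-crossing step draws the diffusion-bridge probability
$\exp(-2(a-x_0)(a-x_1)/s^2 dt)$ of a hidden crossing, removing the leading
bias at any step size. Cohort generation uses plain Euler at
$dt = 10^{-3}$ s: EZ consumes only the first two moments, whose residual
bias at that step is far below between-subject variation. Trials that fail
to absorb within 20 s are resampled and counted.

All randomness flows through R's RNG, so a seed fixes the trial sequence
exactly. Cohort generation derives one substream per subject × task ×
condition from the master seed by a fixed counter scheme, making cohorts
reproducible trial-for-trial regardless of evaluation order.

## The task designs

`build_design()` encodes the four attentional paradigms with their exact
printed constants: 132 spatial-processing trials (44 per eccentricity of
3.5°, 5°, 7°); 146 orienting trials (96 valid/50 invalid, i.e.
65.8%/34.2%); 208 stop-signal trials (112 GO = 53.8%, 96 STOP = 46.2%,
24 per SOA of 200/400/600/800 ms); 186 switching trials (93 per stimulus
size) with the cue colour drawn independently red/green per trial.
Condition counts are invariant to the shuffling seed (tested across seeds).

Where the sources leave the design under-determined we balance: the 44
trials per eccentricity split over 4 orientations × 2 placements as 6/5
cells arranged so each orientation gets 11 and each placement 22; stop
trials split 12/12 by size within each SOA, GO trials 56/56. Because the
cue colour is a per-trial coin flip, switch/repeat counts are stochastic
by design — no switch ratio is imposed.

## The synthetic cohort

`cohort_config()` / `generate_cohort()` produce a complete two-group data
set (19 RP, 13 control) that emulates the statistical structure a real
cohort of this design would have: subject-level parameters drawn around
group × condition means (normal, SD 20% of the mean, truncated at
±2.5 SD and at validity bounds), every planned trial simulated through the
diffusion. Control means are anchored to the printed group statistics
where available (orienting-task control $v \approx 0.49$,
$T_{er} \approx 163$ ms; RP $v \approx 0.365$, $T_{er} \approx 263$ ms;
eccentricity-wise $T_{er}$ at the printed midpoints). The shipped effect
profile is: RP $T_{er}$ = control + 100 ms everywhere; RP $v$ reduced at
7° (×0.7) and in the orienting task (×0.745); RP $a$ ×0.8 in the
switching task; controls carry a large-stimulus $T_{er}$ switching cost
while RP $T_{er}$ is flat across sustained/switching.

Two generating values deserve comment because the sources constrain them
only loosely:

* **Boundary separation.** No $a$ is printed anywhere. The printed RTs
  (~0.7–1.2 s) combined with the printed drifts would force near-ceiling
  accuracy ($P_c > 0.99$), under which 44-trial cells hit $P_c = 1$ almost
  always and moment-based estimation degenerates. We therefore choose $a$
  (0.08–0.10) to keep cell accuracy near 0.87–0.96 — prioritising the
  printed $v$ and $T_{er}$ over RT magnitude — which is the regime in
  which per-cell estimation at these trial counts is well-conditioned.
* **Control switching cost.** The printed condition CIs are compatible
  with anything from no cost to ~360 ms. We ship 80 ms (40 ms for the
  small stimulus): large enough to be detectable at $n = 13$, and below
  the 100 ms RP shift so that RP non-decision time exceeds the control
  one in every condition, as observed.

Stop-signal STOP trials are not diffusion trials: successful inhibition
has no RT. They get a Bernoulli outcome with success probability falling
linearly from 0.95 at SOA 200 ms to 0.55 at 800 ms, reproducing the
SOA-graded accuracy decline; the stop-signal task is excluded from EZ
fitting (only accuracy/RT are analysed there, as in the study design).
Simulated RTs beyond the stimulus window (3000 ms; 1900 ms for GO trials)
become misses with `responded = 0`.

What the generator deliberately does **not** emulate: fixation
instability and eye movements, visual-acuity covariates, sequential
effects (trials are exchangeable within a cell), RT contamination
(no fast guesses or lapses beyond the diffusion itself), and across-trial
parameter variability. Passing recovery and calibration tests therefore
certify the estimator and pipeline under the model's own assumptions —
they do not certify robustness to the contaminants real data carry.

## Preprocessing

`filter_trials()` applies the study's cleaning rule — keep responded
trials with RT in [200, 3000] ms, bounds inclusive (the printed window's
upper end equals the stimulus duration, so exclusive bounds would discard
legitimate responses) — and reports per-reason exclusions. Incorrect
trials are kept at this stage (they count toward accuracy) and dropped
only from RT summaries. `classify_switch()` labels each switching-task
trial by comparing its cue colour with the previous trial's, in
presentation order; each subject's first trial has no predecessor and is
excluded from both conditions. `summarize_condition()` computes the EZ
triple per cell, with the unbiased ($n-1$) variance over correct trials
only, in seconds.

## The statistical layer

The comparison machinery mirrors the study's analysis plan. Standard
tests delegate to base R (`t.test`, `fisher.test`, `cor.test`,
`power.t.test`) behind thin wrappers that enforce the pipeline's error
contracts; two pieces are implemented directly:

* **Mixed-design ANOVA** (`mixed_anova()`): the classical split-plot
  decomposition on subject-level cell means (the conventional unit of
  analysis for this design), one between factor with possibly unequal
  groups, one within factor. The group effect is tested against
  subjects-within-groups; condition and interaction against
  condition × subjects(groups). Components are verified in the tests to
  sum to the total SS and to match `aov(... + Error(subject))` strata on
  random unbalanced tables. A zero error stratum yields a flagged,
  serialisable `NA` rather than an infinite F.
* **Holm–Šidák step-down** (`holm_sidak()`): thresholds
  $1 - (1-\alpha)^{1/(m-i+1)}$ applied to the ascending p-values,
  stopping at the first non-rejection; it rejects a superset of the
  single-step Šidák rule (tested).

The model-fit check (`fit_diagnostics()`) is the squared Pearson
correlation between observed and forward-predicted cell values — accuracy
against predicted $P_c$, mean RT against $MDT + T_{er}$ — pooled across
subject × condition cells per experiment. Pooling across both groups is a
choice (the sources do not state the pooling unit); it is recorded in the
output metadata. Because the per-cell inversion reproduces each cell's
moments exactly, this diagnostic sits near 1 whenever all cells invert
cleanly — it departs from 1 only through edge-corrected and unfit cells,
so it is a data-quality indicator rather than a goodness-of-fit test, and
the low R² values a real (noisier, differently pooled) cohort yields are
not comparable targets. The power calculation `sample_size_two_sample()` returns
the smallest integer group size whose exact t-test power reaches the
target; at $d = 1$, one-tailed $\alpha = 0.05$, power 0.8 this is 14
(the normal approximation gives 12.4; exact power at 13 is 0.797).

## The pipeline

`run_pipeline()` chains generate → label → filter → summarize → fit →
analyze → report, writing `trials.csv`, `truth.csv`, `parameters.csv`,
`filter_report.json`, `stats_report.json`, `fit_diagnostics.json`,
`report.txt` and `run.log`; the log stamps the config's MD5 and the seed,
and identical configurations reproduce byte-identical artifacts (tested).
The orienting task is fitted pooled over valid and invalid trials (the
cue-validity contrast was null and the groups were compared on the
integrated data); this is configurable through the condition labels. A
thin command-line front end (`inst/cli/ezpipeline.R`) exposes
`simulate`, `preprocess`, `fit-ez`, `analyze` and `run-all` subcommands.

## Validation scales and known limitations

The heavier validation checks run at fixed, stated sizes chosen to make
Monte-Carlo tolerances meaningful while keeping the default suite quick:
the simulator oracle at 200,000 trials with $dt = 10^{-4}$ s; parameter
recovery on one full spatial-task cohort (32 subjects × 3 × 44 trials);
type-I calibration and the qualitative-reproduction rates on 100
replicate cohorts each. At these sizes the estimator recovers generating
drifts and boundaries with regression slopes within a few percent of 1,
median absolute $T_{er}$ error under 30 ms at 44-trial cells, a group
main effect holding its nominal 5% false-positive rate, and the shipped
effect profile reproducing the qualitative group findings in nearly all
replicates.

Limitations worth keeping in mind: the EZ inversion is exactly identified,
so model misfit is only detectable through the observed-vs-expected
$R^2$, not within a cell; edge correction biases extreme cells inward;
the empirical group values of the original cohort are not reproducible
targets (no raw data are deposited), so the synthetic defaults encode the
qualitative pattern, not the exact group means; and the stop-signal task
is modelled descriptively (no race-model stop-signal RT is estimated).
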