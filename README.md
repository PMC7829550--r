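# ezdiffusion

EZ-diffusion decomposition of two-choice attentional task performance,
built for studies of attentional deficits in retinitis pigmentosa (RP) —
a hereditary retinal degeneration that progressively destroys the
peripheral visual field. Behavioural slowing in such patients can come
from slower information uptake, more cautious responding, or slower
stimulus encoding; mean RT alone cannot tell these apart. This package
implements the closed-form EZ-diffusion decomposition that separates
them, together with everything needed to run the full analysis: the four
task designs (spatial processing, attentional orienting, stop-signal,
attention switching), a compiled Wiener first-passage simulator, a
synthetic two-group cohort generator, the RT-window preprocessing stage,
and the statistical comparison layer (mixed-design ANOVA with Holm–Šidák
step-down post hoc tests, Fisher's exact test, eccentricity correlations,
fit diagnostics, power analysis).

## The model

A trial is modelled as noisy evidence accumulation between two absorbing
boundaries a distance *a* apart (response caution), starting midway,
drifting at rate *v* (processing efficiency) with within-trial noise *s*;
the observed RT adds a non-decision time *T*<sub>er</sub> (encoding +
motor), so *MRT = MDT + T*<sub>er</sub>. With *y = −va/s²* the unbiased
process has closed-form accuracy, mean and variance of decision times:

    Pc  = 1 / (1 + e^y)
    MDT = (a / 2v) · (1 − e^y) / (1 + e^y)
    VRT = (a s² / 2v³) · (2 y e^y − e^{2y} + 1) / (1 + e^y)²

and the map inverts in closed form: from a cell's (Pc, MRT, VRT),
with L = logit(Pc),

    v = sign(Pc − ½) · s · [ L (Pc² L − Pc L + Pc − ½) / VRT ]^{1/4}
    a = s² L / v,     Ter = MRT − MDT.

`ez_fit()` applies this inversion across a table of subject × condition
cells and returns a classed model object with `print`, `summary`, `coef`,
`predict`, `residuals`, `plot` and `simulate` methods.

## Worked example

Generate a synthetic cohort for the spatial and orienting tasks, run the
whole pipeline, and compare the groups' non-decision times:

```r
library(ezdiffusion)

cfg <- run_config(master_seed = 11,
                  cohort = cohort_config(tasks = c("exp1", "exp2")),
                  fit_tasks = c("exp1", "exp2"))
res <- run_pipeline(cfg, "demo_run")

res$filter_report
#> RT window filter [200, 3000] ms: retained 8553 of 8896 trials (96.14%)
#>   excluded (rt below min): 343

res$fit
#> EZ-diffusion fit (s = 0.1 )
#>   cells: 128  fitted: 128  edge-corrected: 17  negative-Ter flags: 0
#>   v   : median 0.292  [0.097, 0.708]
#>   a   : median 0.099  [0.051, 0.172]
#>   Ter : median 314 ms [169, 636]

e2 <- subset(res$fit$parameters, task_id == "exp2" & !unfit)
t_test_two_sample(e2$ter_ms[e2$group == "RP"],
                  e2$ter_ms[e2$group == "control"])
#> two-sample t-test: statistic = 6.4061, df = 30, p = 4.507e-07
```

Reading the output: 96.1% of trials survive the 200–3000 ms window (the
excluded ones are fast sub-200 ms responses); all 128 subject × condition
cells invert cleanly, with drifts around 0.3 and non-decision times
around 300 ms; and the RP group's estimated non-decision time in the
orienting task is far above the control group's (t(30) = 6.4) — the
synthetic cohort's built-in +100 ms encoding deficit, recovered by the
fitted model. `demo_run/` also contains `parameters.csv` (one row per
cell with v, a, Ter, MDT and flags), `stats_report.json`,
`fit_diagnostics.json` and a human-readable `report.txt`.

A command-line front end with `simulate`, `preprocess`, `fit-ez`,
`analyze` and `run-all` subcommands is installed at
`inst/cli/ezpipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/ezpipeline.R", package="ezdiffusion"))')" run-all --seed 1 --out ezrun
```

## Package layout

* `R/ez-math.R`, `R/ez-fit.R` — closed-form model and the `ez_fit()`
  estimator with its S3 methods
* `src/ddm.cpp`, `R/ddm-simulate.R` — compiled Euler–Maruyama /
  bridge-corrected first-passage simulator
* `R/task-designs.R` — the four experiments' trial-sequence blueprints
* `R/cohort.R` — synthetic cohort configuration and generation
* `R/preprocess.R` — RT-window filter, switch labelling, cell summaries
* `R/stats-tests.R`, `R/mixed-anova.R` — the statistical layer
* `R/pipeline.R`, `inst/cli/ezpipeline.R` — orchestration and CLI
* `vignettes/ez-diffusion-methods.Rmd` — models, assumptions, numerical
  choices and limitations
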