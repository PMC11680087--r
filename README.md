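# equigait

Equine locomotion monitoring from body-worn inertial sensors: per-stride
gait events, limb loads and load-asymmetry indices, computed from five
120 Hz IMUs (one laterally on each cannon bone, one on the saddle girth).

Lameness and overload injuries in sport horses develop under everyday
training loads that force plates cannot observe in the field. `equigait`
turns routine five-sensor IMU trials into objective, per-stride load
measures for walk, trot and canter:

* **Gait events.** The cycle period is estimated from the oscillating pitch
  angle; strides are delimited by the swing-phase peaks of the low-passed
  (20 Hz, second-order Butterworth, zero-phase) sagittal angular velocity;
  within each cycle the first peak of the tri-axial acceleration magnitude
  |a| = √(aₓ² + a_y² + a_z²) marks hoof-on and the most prominent later peak
  marks hoof-off.
* **Stride parameters.** Stride frequency, stance and swing duration, duty
  factor (stance/stride), and the peak impact limb load
  PILL = max |a| at hoof-on (in g; 1 g = 9.81 m s⁻²).
* **Asymmetry indices.** With F, H, L, R the mean PILL of the fore, hind,
  left and right limbs of a trial,

  LongAI = (F − H) / (½(F + H)) · 100 %  (positive → forelimb dominance)

  LatAI = (L − R) / (½(L + R)) · 100 %  (per pair; positive → left dominance)

* **Cohort statistics.** Repeated-measures ANOVA with partial η²
  (Greenhouse–Geisser under Mauchly violation), Tukey post hocs with
  Cohen's d, Shapiro–Wilk/Levene checks, Spearman correlations, and
  Bland–Altman sensor agreement.
* **A synthetic gait simulator** (walk, trot, left/right-lead canter) with
  exact per-stride ground truth, so every stage is testable without any
  recording.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` / `plot_*()` for figures.

## Worked example

Simulate one 40 s trot trial with known per-limb impact loads, run the full
analysis, and compare against the imposed truth:

```r
library(equigait)

spec <- synthetic_spec("trot",
                       impact_peak_g = c(LF = 10.2, RF = 9.8,
                                         LH = 9.0,  RH = 9.4),
                       seed = 42)
sim <- generate_trial(spec)
res <- analyze_trial(sim$trial)

tidy(res$summary)
#>   stride_freq_hz stance_ms swing_ms duty_factor pill_g long_ai_pct lat_ai_fore_pct lat_ai_hind_pct
#> 1          1.301   316.667  453.125       0.412  9.625       8.459           4.225          -4.937
```

Reading the output: the trial runs at 1.30 strides/s with a 317 ms stance
and 453 ms swing (duty factor 0.41 — airborne more than half the stride, as
expected in trot). The mean impact load is 9.6 g. The imposed fore loads
(10.2/9.8 g) against hind (9.0/9.4 g) correspond to LongAI
= (10.0 − 9.2)/9.6 · 100 = +8.3% (forelimb dominance) and LatAI of +4.0%
(fore, left-dominant) and −4.3% (hind, right-dominant); the pipeline
recovers 8.5%, 4.2% and −4.9% from the noisy signals. Against the
simulator's ground truth:

```r
evaluate_events(res$cycles, sim$truth$events)
#>   recall rmse_on_ms rmse_off_ms pill_mare_pct
#> 1 0.9804          0           0        1.4933
```

98% of strides are found, event times are exact to the sample, and the
per-stride load error is 1.5%.

From a shell, the same pipeline is available as subcommands
(`exec/equigait` after install, or `Rscript -e 'equigait::eqg_cli()' --args …`):

```sh
equigait simulate --out sim --horses 20 --trials 4 --seed 1
equigait analyze  --manifest sim/cohort.yaml --out results
equigait evaluate --detected results/stride_table.csv --truth sim/ground_truth.csv
equigait stats    --summary results/trial_summary.csv --out results/stats
equigait print-config
```

`analyze` writes a per-stride table, per-trial summaries, an asymmetry
report and a run log recording every threshold used; failures are isolated
per trial.

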