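# trescore

Objective and subjective adherence scoring for time-restricted eating
(TRE) trials.

Free-living TRE interventions prescribe an eating window — here a
symmetric 3 h reduction of the habitual window, delaying the first and
advancing the last energy intake by 1.5 h each — and then need to know
whether participants actually followed it. Self-report alone is
unreliable precisely where it matters (the unlogged late-evening snack).
`trescore` scores adherence by cross-examining time-stamped diet diaries
against continuous glucose monitoring (CGM), day by day, and summarises
exit-questionnaire responses so objective and subjective rates can be
compared.

## What it computes

For each 24 h eating day (04:00–04:00) of a TRE participant, with
reported window (f, l), baseline mean window W₀, targets (f\*, l\*) and a
±30 min allowance, the day is adherent iff:

1. W₀ − (l − f) ≥ 3 h − 30 min **and** l − f ≤ 12 h (both clauses kept
   as separate booleans);
2. |f − f\*| ≤ 30 min and |l − l\*| ≤ 30 min;
3. the first and last CGM excursion onsets of the day each fall within
   ±30 min of the reported first and last intake.

An eating occasion in the CGM trace is a glucose elevation ≥ 1 mmol/L
above the 30-min pre-onset minimum, sustained ≥ 1 h with no gap over
30 min. Controls (and all baseline days) are adherent while the reported
window stays ≥ 12 h. Adherence percent is (days adherent ÷ days
available) × 100, with the denominator recalculated when sensor data are
missing; phases W0/W2/W5 aggregate to group mean ± SEM, and the
study-level rate is the unweighted mean of the W2 and W5 rates.

Because raw trial data of this kind are rarely available, the package
includes a synthetic cohort generator (`simulate_study()`) with per-day
ground truth — including diary-silent "unreported intake" days that only
the CGM criterion can catch — used to validate the whole chain.

## Worked example

```r
library(trescore)

cfg    <- simulation_config()                    # 8 TRE + 8 control, p = 0.63
cohort <- simulate_study(cfg, seed = 1)
scores <- score_study(cohort$roster, cohort$diary, cohort$cgm, cfg$start_date)
scores
#> <tre_adherence> 16 participants, 784 participant-days
#>
#>    group phase n mean_percent sem days_per_week
#>  CONTROL    W0 8         80.4 4.6           5.6
#>  CONTROL    W2 8         82.1 3.6           5.8
#>  CONTROL    W5 8         82.7 2.5           5.8
#>  CONTROL  Mean 8         82.4 2.3           5.8
#>      TRE    W0 8         80.4 6.0           5.6
#>      TRE    W2 8         61.0 3.7           4.3
#>      TRE    W5 8         62.0 3.5           4.3
#>      TRE  Mean 8         61.5 2.3           4.3
```

Read this as: during baseline (W0) both groups kept their habitual
≥ 12 h windows on ~80% of days (~5.6 d/week). During the intervention the
TRE group met the full criterion set on ~61% of scorable days
(~4.3 d/week) — recovering the generator's true per-day adherence
probability of 0.63 — while controls kept habitual windows ~82% of days.
`tidy(scores)` returns the 784 day-level records with each criterion's
outcome; `glance(scores)` the one-row study summary; `autoplot(scores)`
the phase trajectory. Subjective adherence comes from the questionnaire
module:

```r
q <- questionnaire_table(cohort$questionnaire)
q[q$item == "window_days", c("tre_mean", "ctrl_mean")]
#>   tre_mean ctrl_mean
#> 1     3.75         3
days_to_percent(3)    # control: 3 d/week of a 7-day week
#> [1] 43
```

A full run (ingestion → detection → scoring → tables + threshold log) is
one call: `run_pipeline(list(simulation = list(), seed = 1, out_dir =
"out"))`, or `Rscript inst/scripts/tre-report.R demo out/` from a shell.
`plot_cgm_day()` draws the single-day diagnostic view (glucose curve,
reported intake markers, target-window shading, detected onsets).

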