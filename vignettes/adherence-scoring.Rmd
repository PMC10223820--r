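---
title: "Scoring adherence to a time-restricted eating protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring adherence to a time-restricted eating protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Time-restricted eating (TRE) confines all daily energy intake to a window
of less than 12 h, without prescribing what or how much to eat. Free-living
TRE trials report adherence anywhere from ~63% to 100%, but the number is
usually self-reported, and self-report is exactly what a timing
intervention is most likely to distort: a late-evening snack that breaks
the window is also the easiest thing to leave out of a diary.

`trescore` implements an objective adherence analysis for such trials. It
cross-examines two data streams that are routinely collected anyway —
time-stamped diet diaries from a logging app, and continuous glucose
monitoring (CGM) at a nominal 15-min cadence — and scores every 24 h
period of a 5-week intervention against explicit protocol criteria. A
questionnaire module summarises the subjective side (Likert-scale
perceived adherence), so objective and subjective rates can be compared in
one report.

Because trials of this kind rarely deposit raw participant data, the
package ships a synthetic cohort generator with known per-day ground
truth. Every stage of the pipeline is validated against that ground truth;
the generator is first-class, tested code, not a test fixture.

## The protocol model

Participants are screened on BMI (18.5–29.9 kg/m²), age (18–50 y), blood
pressure (< 140/90 mmHg, strict on both readings) and a habitual eating
window of at least 12 h. The intervention prescribes a **symmetric 3 h
reduction** of the habitual window: relative to the mean first and last
eating times of the last baseline week, the first intake is delayed 1.5 h
and the last advanced 1.5 h. A ±30 min allowance applies throughout.

All clock arithmetic uses an **eating day** that runs 04:00–04:00 local
time, stored as minutes since midnight with values ≥ 1440 denoting
post-midnight intake (01:30 is "25:30", 1530 min). Eating windows can
legitimately cross midnight; the 04:00 cut places both window endpoints on
one continuous span far from where eating times cluster, which is also why
plain arithmetic means of clock times are valid here and circular means
are unnecessary.

### Day-level criteria (TRE group, intervention days)

For a day with reported window $(f, l)$, baseline mean window $W_0$,
targets $(f^\*, l^\*)$ and tolerance $\tau = 30$ min:

1. **window reduced**: $W_0 - (l - f) \ge 3\,\mathrm{h} - \tau$, and
   separately **window ≤ 12 h**: $l - f \le 12$ h. The two clauses are
   stored as distinct booleans because for baselines above 15 h a perfect
   3 h reduction still exceeds 12 h; keeping both visible lets an analyst
   see which clause failed. Both must hold.
2. **times shifted**: $|f - f^\*| \le \tau$ and $|l - l^\*| \le \tau$.
3. **glucose match**: the first and last detected excursion onsets of the
   day each lie within ±30 min of the reported first and last intake. A
   day with adequate sensor coverage but *no* detected excursion fails
   this criterion — the CGM then contradicts the reported intake.

A day is adherent only if all criteria hold. A criterion whose inputs are
missing is `NA`, and the day's adherence is then *missing*, never false.
Control days, and baseline days in both groups, use the habitual rule: the
reported window must remain ≥ 12 h (controls are coded non-adherent below
12 h; no targets exist at baseline, so the TRE criteria cannot apply
there).

### Aggregation

Adherence percent is (days adherent ÷ days available) × 100, where the
denominator counts only days whose adherence could be determined: when
sensor data are missing the denominator is recalculated rather than
counting those days against the participant. Phases are W0 (last baseline
week, day indices −7…−1), W2 (days 1–14) and W5 (days 15–35); group
summaries report mean ± SEM (sample SD over √n) per phase, and the
study-level "Mean" is the **unweighted** mean of W2 and W5 — this
reproduces the conventional summary-table layout. A day-weighted variant
(weights 14 and 21) is available via `combine_phases(weights =)` because
the two definitions genuinely differ (62.65 vs 63.16 for rates 60.1 and
65.2) and reports do not always say which was used. Printed percents and
days-per-week round half-up to one decimal.

Scoring against per-day diary windows is the default. For days without a
diary record, the participant's phase-mean reported window stands in as
the "agreed" eating times (`use_mean_window_fallback = TRUE`), mirroring
analyses that compare each 24 h CGM recording against mean reported eating
times; trials typically require only 7 recorded baseline days and 4 days
per intervention assessment, so diary-less days are the norm in real data.

## Excursion detection

The operational definition of an eating occasion is a glucose elevation of
**≥ 1 mmol/L sustained ≥ 1 h**. The detector makes that rule precise:

- For each candidate onset sample, the **reference** is the minimum
  reading over the 30 min preceding it (truncated at the trace start; the
  very first sample can never anchor an onset because it has no earlier
  reading). A short local reference tracks slow circadian drift without
  absorbing the meal rise itself.
- An excursion is emitted when glucose stays ≥ reference + 1 mmol/L
  *continuously* — no sample below the level, no sensor gap above 30 min —
  for ≥ 60 min. Sustained time is measured from the onset sample to the
  last elevated sample.
- Overlapping or abutting qualifying stretches merge into one excursion
  (if glucose never returns below the level between two stretches, they
  are one physiological event). Returned excursions never overlap.

Elevation is relative, so the detector is invariant to adding a constant
to the whole trace. Dawn (waking) excursions are **not** excluded: the
scoring rules never excluded them, and the default simulated dawn rise
(0.5 mmol/L) sits below the 1 mmol/L threshold in any case. Days with
sensor coverage below 0.5 of expected samples are flagged unavailable —
one cannot certify "elevated for ≥ 1 h" from a mostly-missing day; the
0.5 threshold is a declared, configurable choice.

The detector is verified sample-for-sample against a brute-force oracle
that enumerates every (start, end) pair and checks the elevation predicate
directly (see `tests/testthat/helper-oracle.R`).

## Questionnaire coding

Days-per-week Likert bins code to the midpoints of their printed ranges
(Never 0 → 0, Sometimes 1–2 → 1.5, Approx. half 3–4 → 3.5, Most of the
time 5–6 → 5.5, Always 7 → 7); the ease item codes 1–5 from Extremely
difficult to Extremely easy; the realistic-days item takes exact 0–7
counts; the window-restriction duration bins code to ordinal 1–6. The
coding map is replaceable because published group means are sometimes
finer than midpoint arithmetic can produce, suggesting some instruments
collect exact day counts. Days-per-week convert to percent-of-week by
half-up rounding of 100 d/7 — the convention that reproduces printed
pairs such as 4.3 d → 61% and 3 d → 43%.

Group comparisons use Student's pooled-variance t-test by default
(matching common statistical-software defaults), Welch by flag; both
delegate to `stats::t.test`. The 2×2 sex-ratio test is Pearson's
chi-squared without continuity correction (correction by flag), via
`stats::chisq.test`; zero-margin tables are flagged undefined.

## The synthetic cohort generator

`simulation_config()` defaults are the study conditions the package
emulates, chosen once:

| parameter | default | why |
|---|---|---|
| group sizes | 8 TRE + 8 control | the emulated trial's arms |
| phases | 14 baseline + 35 intervention days | 2-week baseline, 5-week intervention |
| TRE day adherence `adherence_p` | 0.63 | the headline objective adherence scale |
| habitual-day probability | 0.79 | habitual ≥ 12 h windows hold ~79% of days (control overall rate) |
| habitual windows | 12.2–14 h, first ≈ 08:00 ± 30 min | eligibility floor ≥ 12 h; the cap keeps 3 h-reduced targets ≤ 12 h so criterion 1's clauses cannot conflict by construction |
| day-to-day jitter | ±10 min | within the ±30 min allowance with margin for target-derivation noise |
| meal response | peak 3.0 ± 0.5 mmol/L (floor 2.2) at τ = 45 min, tail 240 min | see calibration note below |
| basal glucose | 5 mmol/L | normoglycaemic adults |
| circadian ripple | 0.3 mmol/L, trough ~03:00 | modest 24 h rhythm |
| dawn bump | 0.5 mmol/L at 07:00 ± 30 min | sub-threshold dawn phenomenon in non-diabetics |
| sensor noise | 0.2 mmol/L | flash-sensor error at euglycaemia |
| sensor dropout | 0.05/day | occasional sensor failure; the trial reported missing CGM |
| violation mix | equal thirds | early first intake / late last intake / unreported evening intake |

Each TRE intervention day is behaviourally adherent with probability
`adherence_p`: three meals are placed with first/last intake inside the
allowance of the participant's targets. Non-adherent days draw one
violation mode; the *unreported* mode writes an adherent-looking diary but
adds a late-evening intake 3–5 h after the reported last meal to the CGM
trace only — the scenario in which diary-only scoring must overestimate
adherence and only the glucose-match criterion can object. The targets a
simulated participant follows are derived from their *realized* baseline
diary exactly as the pipeline derives them, mirroring a trial in which
prescribed targets are computed from the recorded baseline.

**Meal-kernel calibration.** The ≥ 1 mmol/L-for-≥ 1 h rule is the study's
operational definition of an eating occasion, which presupposes that
ordinary meals produce excursions the rule can see. With a gamma-like
kernel $A\,(\Delta t/\tau)\,e^{1-\Delta t/\tau}$ peaking at $\tau=45$ min,
a response must peak well above ~2 mmol/L for the elevation to clear a
noisy 2-sample reference minimum by 1 mmol/L across four consecutive
15-min readings; amplitudes drawn at 3.0 ± 0.5 (floor 2.2) keep simulated
meals inside the rule's detectable regime, as an analysis built on this
rule requires, while staying within the physiologic range of mixed-meal
postprandial peaks. Smaller amplitudes make detection of genuinely
adherent days fail sporadically — a property of the rule, worth knowing
when applying it to real sensors.

**What the generator does not emulate**: insulin dynamics, meal
composition or size effects, glycaemic responses that vary by time of day,
within-participant adherence autocorrelation (weekend effects), sensor
drift or compression artefacts, and diary mistiming (reported times are
exact when present). Passing recovery tests therefore show the *scoring
chain* is unbiased under the stated noise model — they do not show the
criteria are robust to diary inaccuracy, which in real data is a
first-order concern and one motivation for the CGM criterion.

## Numerical choices

- Half-up rounding (`round_half_up()`) everywhere a printed value is
  produced; base R's banker's rounding would flip half-cases.
- Duplicate CGM timestamps collapse to their mean; non-positive glucose
  rows are dropped with line numbers; unparseable timestamps are errors.
- `adherence_percent()` of zero scorable days is `NA` with a warning,
  never 0.
- Degenerate inputs: a single-event day is a zero-length window (distinct
  from "no diary data"); an empty cohort writes valid empty files;
  `derive_protocol_targets()` rejects baseline windows shorter than the
  3 h reduction (targets would invert).
- Reproducibility: one master seed spawns independent per-participant
  substreams; identical seeds give byte-identical cohort files.

## Test problem sizes

The suite validates detector–oracle equivalence on 300 random traces of
10–200 samples (exact equality), onset sensitivity on 500 single-meal
days at noise 0.3 mmol/L (≥ 95% within one cadence step), end-to-end
recovery on twenty 8+8 cohorts at `adherence_p = 0.63` (estimates inside
the 95% binomial interval of p at 280 day-observations in ≥ 19 of 20
replicates), exact 100%/0% scores for noise-free p = 1/p = 0 cohorts, and
a ≥ 90% catch rate for unreported-intake violations. These sizes are the
package's chosen validation scale; all are generated in code at test time.

## Limitations

- Criterion 3 inherits the detector's onset granularity (one cadence
  step); at 15-min cadence the ±30 min match tolerance absorbs it, but
  coarser sensors would not be scorable this way.
- The habitual-window rule for controls and baselines is diary-only; CGM
  is not cross-examined there.
- Inferential statistics beyond the two-sample t-test and 2×2 chi-squared
  (e.g. repeated-measures ANOVA across phases) are out of scope; the
  package reports group × phase means and SEMs for use in external
  modelling.
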