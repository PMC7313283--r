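# wearwell

Composite physical well-being scoring from consumer wearable-device data.

Wrist-worn trackers produce months-long daily streams of steps, activity
time by intensity, sleep-phase durations and heart-rate summaries. Public
health studies need those heterogeneous streams condensed into something a
clinician, a policy maker or the wearer can actually read. `wearwell`
implements a transparent, rule-based baseline for that: four domain indices
derived from institutional guideline thresholds, composed into a single
weighted geometric-mean indicator, validated against self-reported
well-being questionnaires.

## The model

For each person and period (ISO week or calendar month), four domain
indices are computed from the aggregated daily measurements:

| index | domain | rule | range |
|---|---|---|---|
| I_w | walking | mean daily steps banded at 5,000 / 7,500 / 10,000 / 12,500 | 1–5 |
| I_p | physical activity | moderate-equivalent weekly minutes (moderate + 2 × vigorous) banded at 30 / 60 / 150 | 1–4 |
| I_s | sleep | mean daily sleep vs the National Sleep Foundation age-stratified bands: recommended 2, "considered appropriate" 1.75, otherwise 1 | {1, 1.75, 2} |
| I_c | cardio-respiratory fitness | VO2max ≈ (hr_max / hr_rest) × 15.3 mL/(kg·min), categorised 1 (very low) … 7 (elite) by gender and age | 1–7 |

The composite indicator is the weighted geometric mean

```
WB_ph = (I_w^w_w · I_p^w_p · I_s^w_s · I_c^w_c)^(1/4)
```

with configurable weights defaulting to w_w = 0.9, w_p = 1.0,
w_s = w_c = 1.05 (sum 4, so the printed fourth root coincides with the
weight-normalised power mean). The geometric form is deliberately sensitive
to a low value in any single domain and needs no prior normalisation of the
differently scaled indices.

Validation correlates `WB_ph` with cumulative scores of two self-report
instruments: a 15-item well-being questionnaire (items 0–4, total 0–60) and
a five-dimension health-status instrument whose 0–100 health-state
assessment maps onto the 1–5 dimension scale as `1 + 4·hsa/100` (total
6–30).

## Worked example

The package ships a hand-built four-person, eight-week cohort in which each
person sits squarely inside a known band of every domain:

```r
library(wearwell)

fx  <- worked_example_fixture()
idx <- score_indices(fx$daily, fx$profiles, period = "weekly")
s   <- composite_series(idx)
dplyr::distinct(s, person_id, i_walk, i_activity, i_sleep, i_cardio, wb_ph)
#>   person_id i_walk i_activity i_sleep i_cardio wb_ph
#> 1       p_a      5          4    2.00        7  4.06
#> 2       p_b      1          1    1.00        3  1.33
#> 3       p_c      3          3    1.75        6  3.12
#> 4       p_d      4          2    2.00        6  3.12
```

`p_a` (13,000 steps/day, 210 moderate min/week, 8 h sleep, resting 50 bpm)
tops every band and composes to 4.06; `p_b` (3,000 steps, 21 min/week, 10 h
sleep at age 70, resting 80 bpm) bottoms out at 1.33. The geometric mean
keeps `p_c` and `p_d` apart from `p_a` despite decent single domains: one
weak index drags the composite down by design.

An end-to-end run on a simulated cohort (50 people, 6 months of daily
records, questionnaires driven by the same latent well-being level):

```r
coh   <- generate_cohort(cohort_config(seed = 42))
idx   <- score_indices(coh$daily, coh$profiles, period = "monthly")
s     <- composite_series(idx)
pairs <- pair_responses(score_eq5(coh$eq5), s)
correlate_pairs(pairs)
#> Composite vs eq5 correlation (pearson)
#>   r = 0.905, p = 8.95e-23, n = 59
```

The positive correlation says the composite tracks the latent level the
generator planted; on real cohorts, where questionnaires measure much more
than physical well-being, correlations are expected to be far weaker.

A thin command-line front end (`inst/cli/wearwell.R`) exposes the same
pipeline as `score`, `validate` and `simulate` subcommands over CSV/YAML
files.

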