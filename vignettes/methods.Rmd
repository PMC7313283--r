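---
title: "Methods: rule-based composite scoring of physical well-being"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based composite scoring of physical well-being}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearwell)
```

## The model and its assumptions

`wearwell` implements a knowledge-driven baseline model of physical
well-being. Instead of fitting parameters to data, it encodes long-standing
institutional guidelines as threshold rules, scores each of four behavioural
domains on its own small ordinal scale, and composes the scores into one
indicator. The design assumptions are:

* daily wearable summaries (steps, activity seconds by intensity, sleep
  time, resting and maximal heart rate) are accurate enough that banding
  them against guideline thresholds is meaningful;
* a period of one ISO week or one calendar month is the natural unit of
  "habitual" behaviour — single days are too volatile to score;
* the four domains are each positively related to physical well-being, and
  a deficit in any one of them matters even when the others are strong.

The third assumption motivates the weighted **geometric** mean

$$WB_{ph} = \left(I_w^{w_w} \cdot I_p^{w_p} \cdot I_s^{w_s} \cdot
I_c^{w_c}\right)^{1/r},$$

which is strictly increasing in every index but disproportionately pulled
down by a low factor, and which combines the differently scaled indices
(1–5, 1–4, 1–2, 1–7) without prior normalisation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| weights `w_w, w_p, w_s, w_c` | 0.9, 1.0, 1.05, 1.05 | – | walking down-weighted for known step over-counting by wrist trackers; sleep and cardio up-weighted for metabolic/cardiac risk relevance. Stored in a YAML config, not code. |
| `root_mode` | `fixed_4` | – | the literal fourth root. The defaults sum to exactly 4, so it equals the `weight_sum` power-mean mode; with non-default weights `weight_sum` restores the min–max mean-value property and weight-scale invariance. |
| `period` | monthly | – | calendar-aligned periods give reproducible labels; weekly available for finer series. |
| `min_coverage` | 4/7 weekly, 15/31 monthly | fraction of days | below roughly half coverage a period mean is too fragile; such periods keep their row but score `NA` rather than being silently extrapolated. |
| `vo2_rest` | window mean | – | the resting-rate summary entering the VO2max ratio; window minimum available, since some devices report a noisier "lowest rate". |
| vigorous equivalence | 2 | – | vigorous minutes count double, consistent with the paired guideline thresholds (150/75, 60–149/30–74, 30–59/15–29). |
| pairing policy | nearest monthly composite within ±45 days | days | questionnaires are sparse relative to an 11-month wearable stream; ±45 days spans adjacent months without reaching across seasons. `same_month` available for stricter pairing. |

## Threshold tables and their completion

The step, activity and fitness bands are closed on the lower bound of the
higher band, matching their "at least / or more" phrasing: exactly 12,500
steps scores 5, exactly 150 moderate-equivalent minutes scores 4, a VO2max
exactly at a cut-point takes the higher category.

The sleep recommendation table is printed as partially open bands (adults:
appropriate "6 h", recommended "7 to 9 h") that leave gaps such as 6–7 h
uncovered. The packaged table completes them by continuity: each
"considered appropriate" band extends to the adjacent recommended bound,
closed on the side away from the recommended range, so for adults
appropriate = [6, 7) ∪ (9, 10] and not-recommended is everything below 6 or
above 10 hours. The three classes then partition (0, 24] hours for every
age category, which the loader validates. Ages at a category boundary take
the older category (lower bound inclusive); ages beyond the oldest bracket
use the older-adults row.

The cardio-fitness normative table (gender × age bracket × six ascending
cut-points mapping VO2max to categories 1–7) ships as an editable YAML
file. The packaged file is a **synthetic** stand-in with the documented
shape of published aerobic-fitness norms (male above female by about
5 mL/(kg·min), declining 3–4 per decade, ages 6–75); its filename carries
the `_synthetic` marker and production use should substitute licensed
values. All scoring behaviour (monotonicity, floor/ceiling, age clamping,
averaged cut-points for unspecified gender) is independent of the exact cut
values.

Maximal heart rate prefers the device-observed maximum over the scoring
window when at least one reading exists and falls back to the crude
220 − age estimate otherwise: an observed maximum is individual data, the
formula is a population default.

## Aggregation and standard scores

Activity seconds convert to weekly-equivalent minutes as the mean daily
minutes × 7, so a 30-day month and a partially covered week are banded on
the same footing as a complete week. Steps and sleep aggregate as the mean
per contributing day. Duplicated person-days are a schema error, not data.

The complementary data-driven route — standard scores
`z = (x − centre)/spread` within gender × decade norm strata (whole-sample
fallback below 5 members), combined by weighted linear aggregation — is
provided for exploratory comparison of individuals against their norm
group. The median and geometric-mean centres exist for skewed variables;
the default stays mean/sd. A zero-spread stratum yields an undefined score
(`NA`), never an exception.

## The synthetic cohort

The generator exists to exercise the full pipeline without any real cohort.
Each person receives a latent well-being level `L` (truncated normal on
0–1, default mean 0.55, sd 0.2); every stream is a noisy monotone function
of `L`:

* steps: negative-binomial daily counts, person mean 2,000 → 15,000 as `L`
  rises, times a configurable device overestimation factor;
* activity: gamma daily moderate/vigorous seconds with weekly totals
  crossing all four guideline bands across the cohort;
* sleep: normal daily hours around a person mean that is in the recommended
  band at high `L` and drifts short or long (random direction) at low `L`;
* heart rate: resting rate falling from ~78 to ~53 bpm with `L`; maximal
  rate near 220 − age;
* questionnaires: items, dimensions and the health-state assessment are
  discretised from `L` plus noise with standard deviation
  `questionnaire_sd` (default 0.15).

Whole person-days drop out at the missingness rate (default 0.1). One seed
drives a single generator for the entire run, so outputs are byte-identical
per configuration.

What the generator does **not** emulate: circadian intra-day structure,
seasonality, device-specific noise beyond the single step bias, and the
dominance of non-physical content in real well-being questionnaires. A
passing end-to-end test therefore shows that the pipeline recovers a
planted monotone latent signal — not that real questionnaires correlate
this strongly with wearable-derived composites; on field data the published
correlations for instruments of this kind are far smaller.

## Degenerate inputs and edge behaviour

* A period missing any one index is never partially composed; its
  composite is `NA` and flagged, because dropping a factor from a geometric
  mean biases it upward exactly when a domain is weak.
* Index values must be strictly positive (they are, by construction of the
  scales); zero or negative values are a domain error.
* Correlation with fewer than 3 pairs or zero variance on either side
  returns an undefined result object rather than raising.
* `hr_max < hr_rest` yields a warning but still computes — transient device
  artefacts should be visible, not fatal.
* Unspecified gender scores fitness against averaged male/female
  cut-points rather than refusing.

## Problem sizes

The shipped tests score a hand-built 4-person × 8-week golden cohort,
sweep each scorer against brute-force band oracles on 10,000 random inputs,
verify composite monotonicity on a 10,000-point sweep, and run the
simulate → score → validate loop on 50 persons × 180 days at three
questionnaire noise levels (0.05, 0.4, 1.0) under fixed seeds. These sizes
give stable verdicts for threshold rules and rank-order properties while
keeping the whole suite in the tens of seconds.

## Known limitations

* The domain indices are coarse ordinal scales; small behaviour changes
  within a band are invisible by design.
* The VO2max estimator is a population-level heuristic; its error for any
  individual is large, which is one reason cardio fitness enters as a 1–7
  category rather than a continuous value.
* Calorie-based activity scoring and sleep-phase (REM/deep) quality
  modelling are out of scope, as is any imputation of missing days.
* Repeated questionnaire fillings by one person enter validation as
  independent pairs; with 2–3 fillings per repeat respondent the effective
  sample is slightly overstated.
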