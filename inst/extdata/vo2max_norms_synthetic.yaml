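# SYNTHETIC cardio-respiratory fitness normative table.
#
# Maps estimated VO2max (mL/(kg*min)) to a 1-7 fitness category
# (1 very low, 2 low, 3 fair, 4 moderate, 5 good, 6 very good, 7 elite)
# per gender and age bracket, ages 6-75. The six cut-points per cell are
# ascending lower bounds of categories 2..7; below the first cut-point the
# category is 1, at or above the last it is 7.
#
# These cut values are a synthetic stand-in patterned on the shape of
# published aerobic-fitness norms (male > female by roughly 5 mL/(kg*min),
# declining 3-4 per decade of age). Replace this file with licensed
# normative values for production use; the scoring code only requires the
# structure (strictly increasing cuts per gender x age cell).
male:
  - {age_min: 6,  age_max: 13, cuts: [30, 35, 40, 45, 50, 55]}
  - {age_min: 13, age_max: 20, cuts: [32, 38, 44, 49, 54, 60]}
  - {age_min: 20, age_max: 30, cuts: [32, 37, 42, 47, 52, 57]}
  - {age_min: 30, age_max: 40, cuts: [30, 35, 40, 45, 50, 55]}
  - {age_min: 40, age_max: 50, cuts: [28, 33, 38, 43, 48, 53]}
  - {age_min: 50, age_max: 60, cuts: [26, 31, 35, 40, 45, 50]}
  - {age_min: 60, age_max: 70, cuts: [23, 27, 31, 36, 41, 46]}
  - {age_min: 70, age_max: 76, cuts: [21, 25, 29, 33, 38, 43]}
female:
  - {age_min: 6,  age_max: 13, cuts: [27, 32, 37, 42, 47, 52]}
  - {age_min: 13, age_max: 20, cuts: [28, 33, 38, 43, 49, 54]}
  - {age_min: 20, age_max: 30, cuts: [27, 32, 37, 42, 47, 52]}
  - {age_min: 30, age_max: 40, cuts: [25, 30, 35, 40, 45, 50]}
  - {age_min: 40, age_max: 50, cuts: [23, 28, 33, 38, 43, 48]}
  - {age_min: 50, age_max: 60, cuts: [21, 26, 30, 35, 40, 45]}
  - {age_min: 60, age_max: 70, cuts: [19, 23, 27, 31, 36, 41]}
  - {age_min: 70, age_max: 76, cuts: [17, 21, 25, 29, 34, 39]}
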