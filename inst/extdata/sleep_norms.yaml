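# US National Sleep Foundation age-stratified sleep-duration recommendations.
# Per age category: the recommended band, and the "considered appropriate"
# bands below and above it (hours per 24 h). Durations outside every band are
# not recommended. The loader completes the printed bands by continuity so
# the three classes partition (0, 24] hours (see package documentation).
categories:
  - name: newborns
    age_min: 0
    age_max: 0.3333333333333333
    recommended: [14, 17]
    appropriate_low: [11, 13]
    appropriate_high: [18, 19]
  - name: infants
    age_min: 0.3333333333333333
    age_max: 1
    recommended: [12, 15]
    appropriate_low: [10, 11]
    appropriate_high: [16, 18]
  - name: toddlers
    age_min: 1
    age_max: 3
    recommended: [11, 14]
    appropriate_low: [9, 10]
    appropriate_high: [15, 16]
  - name: preschoolers
    age_min: 3
    age_max: 6
    recommended: [10, 13]
    appropriate_low: [8, 9]
    appropriate_high: [14, 14]
  - name: school_aged_children
    age_min: 6
    age_max: 14
    recommended: [9, 11]
    appropriate_low: [7, 8]
    appropriate_high: [12, 12]
  - name: teenagers
    age_min: 14
    age_max: 18
    recommended: [8, 10]
    appropriate_low: [7, 7]
    appropriate_high: [11, 11]
  - name: young_adults
    age_min: 18
    age_max: 26
    recommended: [7, 9]
    appropriate_low: [6, 6]
    appropriate_high: [10, 11]
  - name: adults
    age_min: 26
    age_max: 65
    recommended: [7, 9]
    appropriate_low: [6, 6]
    appropriate_high: [10, 10]
  - name: older_adults
    age_min: 65
    age_max: .inf
    recommended: [7, 8]
    appropriate_low: [5, 6]
    appropriate_high: [9, 9]
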