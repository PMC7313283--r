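# Default composite weight factors for the four domain indices.
# Walking is down-weighted for the known step-count overestimation of
# consumer trackers; sleep and cardio fitness are up-weighted for their
# importance in metabolic and respiratory risk.
walking: 0.9
activity: 1.0
sleep: 1.05
cardio: 1.05
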