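arm,cohort,male,female
TDR,retrospective,29,13
MI_TLIF,retrospective,57,22
O_TLIF,retrospective,51,24
TDR,prospective,8,3
MI_TLIF,prospective,16,9
O_TLIF,prospective,14,9
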