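arm,stratum,symbol
TDR,good,+/-
TDR,poor,+/-
MI_TLIF,good,+
MI_TLIF,poor,+/-
O_TLIF,good,-
O_TLIF,poor,+
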