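arm,cohort,level,count
TDR,retrospective,L3-L4,1
TDR,retrospective,L4-L5,17
TDR,retrospective,L5-S1,24
MI_TLIF,retrospective,L3-L4,9
MI_TLIF,retrospective,L4-L5,28
MI_TLIF,retrospective,L5-S1,34
MI_TLIF,retrospective,L5-L6,3
MI_TLIF,retrospective,L6-S1,5
O_TLIF,retrospective,L2-L3,1
O_TLIF,retrospective,L3-L4,8
O_TLIF,retrospective,L4-L5,27
O_TLIF,retrospective,L5-S1,36
O_TLIF,retrospective,L6-S1,3
TDR,prospective,L4-L5,4
TDR,prospective,L5-S1,7
MI_TLIF,prospective,L3-L4,2
MI_TLIF,prospective,L4-L5,9
MI_TLIF,prospective,L5-S1,14
O_TLIF,prospective,L3-L4,2
O_TLIF,prospective,L4-L5,9
O_TLIF,prospective,L5-S1,12
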