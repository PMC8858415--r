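arm,cohort,variable,me,q1,q3,lower,upper,integer_valued,source
TDR,retrospective,age,35,32,42,18,80,TRUE,published
TDR,retrospective,bmi,25.6,23.1,29.6,15,45,FALSE,published
MI_TLIF,retrospective,age,37,33,48,18,80,TRUE,published
MI_TLIF,retrospective,bmi,26.1,23.3,29.6,15,45,FALSE,published
O_TLIF,retrospective,age,43,35,54,18,80,TRUE,published
O_TLIF,retrospective,bmi,26.5,23.6,29.9,15,45,FALSE,published
TDR,prospective,age,34,30,39,18,80,TRUE,published
TDR,prospective,bmi,24.5,23.0,28.8,15,45,FALSE,published
MI_TLIF,prospective,age,36,34,41,18,80,TRUE,published
MI_TLIF,prospective,bmi,26.4,23.7,29.2,15,45,FALSE,published
O_TLIF,prospective,age,45,37,55,18,80,TRUE,published
O_TLIF,prospective,bmi,27.0,24.1,29.2,15,45,FALSE,published
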