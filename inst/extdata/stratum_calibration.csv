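arm,stratum,variable,me,q1,q3,lower,upper,integer_valued,source
TDR,good,odi_m24,6,6,8,0,100,TRUE,published
TDR,good,vas_back_m24,6,5,8,0,100,TRUE,published
TDR,good,vas_leg_m24,4,3,5,0,100,TRUE,published
TDR,good,linear_translation,2,1,4,0,NA,FALSE,published
TDR,good,sagittal_angulation,4,3,5,0,NA,FALSE,published
TDR,good,general_lordosis,30,28,36,NA,NA,FALSE,published
TDR,good,ivd_height,10,9,13,1,NA,FALSE,published
TDR,good,adc,1540,1280,1760,1,NA,FALSE,published
TDR,good,facet_angle,50,44,59,10,170,FALSE,published
TDR,good,pfirrmann,2,1,2,1,5,TRUE,published
TDR,good,fujiwara,1,1,2,1,4,TRUE,published
TDR,poor,odi_m24,16,16,18,0,100,TRUE,published
TDR,poor,vas_back_m24,14,14,16,0,100,TRUE,published
TDR,poor,vas_leg_m24,16,14,18,0,100,TRUE,published
TDR,poor,linear_translation,6,5,7,0,NA,FALSE,published
TDR,poor,sagittal_angulation,7,6,8,0,NA,FALSE,published
TDR,poor,general_lordosis,30,26,38,NA,NA,FALSE,published
TDR,poor,ivd_height,6,5,9,1,NA,FALSE,published
TDR,poor,adc,1050,800,1150,1,NA,FALSE,published
TDR,poor,facet_angle,69,62,74,10,170,FALSE,published
TDR,poor,pfirrmann,3,3,4,1,5,TRUE,published
TDR,poor,fujiwara,2,1,2,1,4,TRUE,published
MI_TLIF,good,odi_m24,8,6,8,0,100,TRUE,published
MI_TLIF,good,vas_back_m24,9,8,10,0,100,TRUE,published
MI_TLIF,good,vas_leg_m24,6,5,7,0,100,TRUE,published
MI_TLIF,good,linear_translation,7,4,11,0,NA,FALSE,published
MI_TLIF,good,sagittal_angulation,8,6,9,0,NA,FALSE,published
MI_TLIF,good,general_lordosis,32,28,36,NA,NA,FALSE,published
MI_TLIF,good,ivd_height,6,5,8,1,NA,FALSE,published
MI_TLIF,good,adc,1180,980,1230,1,NA,FALSE,published
MI_TLIF,good,facet_angle,70,62,78,10,170,FALSE,published
MI_TLIF,good,pfirrmann,3,3,4,1,5,TRUE,published
MI_TLIF,good,fujiwara,3,2,3,1,4,TRUE,published
MI_TLIF,poor,odi_m24,26,20,28,0,100,TRUE,published
MI_TLIF,poor,vas_back_m24,24,22,26,0,100,TRUE,published
MI_TLIF,poor,vas_leg_m24,22,21,23,0,100,TRUE,published
MI_TLIF,poor,linear_translation,3,2,3,0,NA,FALSE,published
MI_TLIF,poor,sagittal_angulation,3,2,3,0,NA,FALSE,published
MI_TLIF,poor,general_lordosis,32,23,38,NA,NA,FALSE,published
MI_TLIF,poor,ivd_height,10,9,12,1,NA,FALSE,published
MI_TLIF,poor,adc,1320,1240,1520,1,NA,FALSE,published
MI_TLIF,poor,facet_angle,52,48,56,10,170,FALSE,published
MI_TLIF,poor,pfirrmann,3,3,5,1,5,TRUE,published
MI_TLIF,poor,fujiwara,3,3,4,1,4,TRUE,published
O_TLIF,good,odi_m24,8,8,10,0,100,TRUE,published
O_TLIF,good,vas_back_m24,10,10,12,0,100,TRUE,published
O_TLIF,good,vas_leg_m24,7,7,8,0,100,TRUE,published
O_TLIF,good,linear_translation,7,5,10,0,NA,FALSE,published
O_TLIF,good,sagittal_angulation,8,6,9,0,NA,FALSE,published
O_TLIF,good,general_lordosis,34,29,41,NA,NA,FALSE,published
O_TLIF,good,ivd_height,4,3,7,1,NA,FALSE,published
O_TLIF,good,adc,670,450,930,1,NA,FALSE,published
O_TLIF,good,facet_angle,69,61,82,10,170,FALSE,published
O_TLIF,good,pfirrmann,3,3,5,1,5,TRUE,published
O_TLIF,good,fujiwara,3,3,4,1,4,TRUE,published
O_TLIF,poor,odi_m24,32,28,36,0,100,TRUE,published
O_TLIF,poor,vas_back_m24,29,27,30,0,100,TRUE,published
O_TLIF,poor,vas_leg_m24,24,22,25,0,100,TRUE,published
O_TLIF,poor,linear_translation,3,2,4,0,NA,FALSE,published
O_TLIF,poor,sagittal_angulation,3,2,4,0,NA,FALSE,published
O_TLIF,poor,general_lordosis,30,26,39,NA,NA,FALSE,published
O_TLIF,poor,ivd_height,10,8,14,1,NA,FALSE,published
O_TLIF,poor,adc,1170,1080,1660,1,NA,FALSE,published
O_TLIF,poor,facet_angle,52,49,56,10,170,FALSE,published
O_TLIF,poor,pfirrmann,3,2,3,1,5,TRUE,published
O_TLIF,poor,fujiwara,3,2,3,1,4,TRUE,published
ALL,all,odi_pre,52,44,60,0,100,TRUE,assumed
ALL,all,vas_back_pre,70,60,80,0,100,TRUE,assumed
ALL,all,vas_leg_pre,60,50,70,0,100,TRUE,assumed
ALL,all,height_loss_fraction,0.5,0.45,0.55,0.3333334,0.6666666,FALSE,assumed
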