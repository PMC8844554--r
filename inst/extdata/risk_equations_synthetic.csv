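equation,form,shape,term,estimate,ref
ihd,exponential,NA,intercept,-4.605,0
ihd,exponential,NA,age,0.020,65
ihd,exponential,NA,hba1c,0.080,8
ihd,exponential,NA,ldl,0.150,2.3
mi,exponential,NA,intercept,-4.423,0
mi,exponential,NA,age,0.030,65
mi,exponential,NA,hba1c,0.100,8
mi,exponential,NA,sbp,0.006,135
mi,exponential,NA,hist_ihd,0.350,0
chf,exponential,NA,intercept,-4.828,0
chf,exponential,NA,age,0.050,65
chf,exponential,NA,bmi,0.030,32
chf,exponential,NA,hist_mi,0.600,0
stroke,exponential,NA,intercept,-5.116,0
stroke,exponential,NA,age,0.050,65
stroke,exponential,NA,sbp,0.010,135
stroke,exponential,NA,hist_mi,0.300,0
amputation,exponential,NA,intercept,-5.809,0
amputation,exponential,NA,hba1c,0.120,8
amputation,exponential,NA,hist_ulcer,1.000,0
blindness,exponential,NA,intercept,-5.521,0
blindness,exponential,NA,hba1c,0.150,8
blindness,exponential,NA,age,0.020,65
renal_failure,weibull,1.4,intercept,-7.131,0
renal_failure,weibull,1.4,egfr,-0.030,75
renal_failure,weibull,1.4,sbp,0.008,135
ulcer,exponential,NA,intercept,-5.521,0
ulcer,exponential,NA,hba1c,0.100,8
death,exponential,NA,intercept,-4.423,0
death,exponential,NA,age,0.075,65
death,exponential,NA,hist_mi,0.500,0
death,exponential,NA,hist_stroke,0.450,0
death,exponential,NA,hist_chf,0.600,0
death,exponential,NA,hist_renal_failure,0.900,0
death,exponential,NA,hist_amputation,0.400,0
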