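complication,cost_event,cost_ongoing,utility_event,utility_ongoing
ihd,14000,2800,0.040,0.020
mi,25000,3000,0.055,0.034
chf,16000,3500,0.100,0.050
stroke,30000,5000,0.120,0.060
amputation,35000,4000,0.280,0.110
blindness,8000,2500,0.070,0.030
renal_failure,60000,50000,0.260,0.110
ulcer,6000,1500,0.100,0.040
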