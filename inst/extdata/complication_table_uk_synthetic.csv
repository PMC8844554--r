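complication,cost_event,cost_ongoing,utility_event,utility_ongoing
ihd,4600,900,0.040,0.020
mi,8200,1000,0.055,0.034
chf,5300,1200,0.100,0.050
stroke,9900,1700,0.120,0.060
amputation,11500,1300,0.280,0.110
blindness,2600,800,0.070,0.030
renal_failure,19800,16500,0.260,0.110
ulcer,2000,500,0.100,0.040
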