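term,level,decrement
mobility,2,0.050
mobility,3,0.300
self_care,2,0.055
self_care,3,0.250
usual_activities,2,0.040
usual_activities,3,0.150
pain_discomfort,2,0.045
pain_discomfort,3,0.260
anxiety_depression,2,0.040
anxiety_depression,3,0.210
any3,NA,0.050
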