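term,level,decrement
mobility,2,0.075
mobility,3,0.320
self_care,2,0.090
self_care,3,0.220
usual_activities,2,0.040
usual_activities,3,0.100
pain_discomfort,2,0.110
pain_discomfort,3,0.350
anxiety_depression,2,0.080
anxiety_depression,3,0.240
any3,NA,0.200
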