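service,version,threshold,se,sp,acc
AI1,1,0.57,0.53,0.84,0.83
AI1,2,0.78,0.68,0.81,0.81
AI1,3,0.79,0.72,0.84,0.84
AI2,1,0.44,0.58,0.84,0.83
AI2,2,0.42,0.66,0.76,0.75
AI2,3,0.44,0.60,0.79,0.78
AI3,1,0.20,0.68,0.75,0.75
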