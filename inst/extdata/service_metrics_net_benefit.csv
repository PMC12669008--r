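service,version,threshold,se,sp,acc
AI1,1,0.17,0.80,0.49,0.50
AI1,2,0.51,0.88,0.49,0.50
AI1,3,0.35,0.91,0.48,0.50
AI2,1,0.21,0.85,0.51,0.52
AI2,2,0.21,0.84,0.50,0.51
AI2,3,0.19,0.99,0.50,0.51
AI3,1,0.60,0.85,0.49,0.50
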