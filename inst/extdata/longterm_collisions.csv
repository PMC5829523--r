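id,day,deliberate,accidental,hours_in_pwc,hours_driving
C1,1,3,3,5.45,1.04
C1,2,1,17,3.13,0.83
C1,3,1,23,3.03,1.63
C2,1,4,14,5.2,2.98
C2,2,0,8,0.97,0.73
C2,3,1,32,10.35,3.79
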