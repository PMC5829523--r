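obstacle,class,A1,A2,A3,A4,A5,A6,A7,A8,A9,A10,A11
door,A,0,0,2,0,3,0,0,1,0,0,1
door,D,0,2,6,2,5,0,4,0,0,0,0
door,C,0,0,2,0,2,4,1,0,0,0,NA
doorway_frame,A,0,1,2,1,10,0,0,2,4,10,2
doorway_frame,D,0,0,1,0,0,0,0,0,0,0,0
doorway_frame,C,0,0,3,1,2,2,0,0,0,0,0
wall,A,0,0,0,1,4,0,0,0,0,5,1
wall,D,0,0,0,0,2,0,0,0,0,0,0
wall,C,0,0,1,1,0,0,1,0,0,0,0
furniture,A,0,0,0,1,3,0,1,1,4,10,0
furniture,D,0,0,0,0,0,0,0,0,0,0,0
furniture,C,0,0,1,0,1,2,2,0,0,0,0
people,A,0,0,0,0,1,0,0,0,2,3,0
people,D,0,0,0,0,0,0,0,0,0,0,0
people,C,0,0,2,0,2,5,0,0,0,0,0
road,A,0,0,1,1,3,0,0,2,1,5,1
road,D,0,0,1,0,4,0,3,0,0,0,0
road,C,0,0,1,0,1,0,0,0,0,0,0
hours_in_pwc,H,16,18,8.5,5,16,10,12,12,5,NA,2
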