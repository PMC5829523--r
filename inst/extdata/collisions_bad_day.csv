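obstacle,class,A1,A2,A3,A4,A5,A6,A7,A8,A9,A10,A11
door,A,1,0,5,0,7,0,2,NA,4,0,NA
door,D,1,2,4,2,3,0,10,NA,0,0,NA
door,C,1,0,5,2,4,2,3,NA,0,0,NA
doorway_frame,A,1,1,6,5,6,0,3,NA,8,5,NA
doorway_frame,D,1,0,1,0,1,0,0,NA,0,0,NA
doorway_frame,C,1,0,6,2,2,0,4,NA,0,0,NA
wall,A,1,0,2,1,10,0,2,NA,0,1,NA
wall,D,0,0,1,0,2,0,0,NA,0,0,NA
wall,C,0,0,3,2,1,1,6,NA,0,0,NA
furniture,A,1,0,2,4,11,1,2,NA,8,5,NA
furniture,D,0,0,1,0,2,0,0,NA,0,0,NA
furniture,C,0,0,4,2,1,2,5,NA,0,0,NA
people,A,0,0,5,1,2,1,1,NA,4,0,NA
people,D,0,0,1,0,0,0,0,NA,0,0,NA
people,C,0,0,1,0,2,9,6,NA,0,0,NA
road,A,0,0,3,3,4,3,1,NA,2,1,NA
road,D,0,0,1,0,2,0,4,NA,0,0,NA
road,C,0,0,1,0,1,6,2,NA,0,0,NA
hours_in_pwc,H,12,18,4.5,7,16,15,16,NA,2,NA,NA
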