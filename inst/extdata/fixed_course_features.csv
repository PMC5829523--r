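id,run,fft_hz,smoothness,fra,frb,fla,flb,rra,rrb,rla,rlb,vel_fr,vel_fl,vel_rr,vel_rl,obst_fr,obst_fl,obst_rr,obst_rl,drive_pct,total_s
B1,1,1.73,1.69,17,74,13,76,10,44,10,13,8,11,13,18,27,32,34,41,80,111
B1,2,1.19,1.69,14,73,13,69,42,116,5,8,8,10,11,8,25,25,35,32,69,100
B1,3,1.14,1.65,24,97,21,85,23,76,17,119,8,8,8,15,34,28,45,32,99,146
B1,4,1.95,1.53,15,80,16,80,17,55,9,26,8,8,8,7,33,30,37,35,100,122
B2,1,1.19,2.24,29,100,31,95,25,72,10,22,11,13,8,10,33,31,34,31,99,145
B2,2,1.3,2.13,24,86,28,90,12,48,9,36,13,10,12,8,32,33,36,41,97,146
B2,3,1.08,2.49,29,97,34,99,5,25,21,55,12,13,11,20,33,29,34,44,98,143
B2,4,1.19,2.42,28,99,32,98,16,59,44,112,12,13,8,8,38,32,35,37,98,152
B3,1,1.84,2.41,29,90,18,73,17,31,8,25,11,11,10,18,37,33,38,35,100,119
B3,2,1.84,2.41,30,94,19,74,4,19,1,7,8,13,7,10,37,36,39,35,99,118
B3,3,1.46,2.5,28,81,19,76,9,35,4,16,8,15,9,14,40,33,36,42,96,110
B3,4,1.73,2.82,28,86,24,74,13,40,10,27,11,13,12,18,39,35,35,35,97,120
B4,1,1.41,2.18,25,96,20,71,21,63,34,84,11,13,10,37,30,36,38,32,98,116
B4,2,1.9,2.02,26,87,20,74,13,45,6,20,8,8,10,13,35,39,37,40,100,112
B4,3,2.01,1.71,26,90,18,67,15,55,1,8,8,8,8,12,31,39,38,46,99,110
B4,4,1.84,1.89,25,86,19,70,17,57,3,17,10,10,7,7,34,36,38,41,100,111
B5,1,1.03,4.49,42,105,32,86,55,127,42,120,21,14,7,31,35,41,37,31,79,125
B5,2,3.36,3.87,43,112,35,103,55,127,8,24,15,16,15,7,35,41,35,37,99,154
B5,3,1.3,3.23,46,114,39,103,21,50,54,126,12,15,5,12,35,37,40,27,100,130
B5,4,1.52,2.72,39,109,38,106,9,35,0,0,8,10,5,0,39,34,36,0,100,127
B6,1,4.66,4.05,42,110,35,103,43,127,22,44,13,10,12,18,38,42,25,34,66,115
B6,2,1.46,3.62,39,109,41,109,35,117,8,24,13,10,7,13,35,30,43,35,78,111
B6,3,1.08,3.24,41,112,38,108,14,41,21,48,11,8,8,26,33,31,36,36,91,122
B6,4,1.41,3.33,32,105,28,86,9,26,21,46,11,11,8,15,36,31,38,45,90,115
B7,1,1.03,2.16,24,96,22,68,6,28,26,10,12,12,6,17,31,31,41,23,100,137
B7,2,1.03,2.15,29,102,21,74,14,39,13,26,14,15,9,18,30,32,40,38,100,149
B7,3,1.57,2.58,24,98,27,83,22,50,17,61,15,15,9,33,31,33,38,26,100,159
B7,4,1.08,2.49,24,94,21,76,16,44,12,37,18,15,9,19,33,38,39,39,99,153
B8,1,1.19,1.85,23,91,16,74,19,48,3,10,10,10,6,6,35,35,33,45,89,169
B8,2,1.25,2.02,27,101,22,70,8,18,26,6,10,10,6,39,40,33,38,25,95,150
B8,3,1.08,1.72,28,88,19,79,45,116,6,6,10,10,6,6,34,34,36,39,99,130
B8,4,1.46,2.11,27,93,26,74,40,94,22,10,10,12,6,10,38,32,38,36,97,142
B9,1,1.25,2.3,25,86,22,70,28,80,17,81,15,14,10,17,34,33,41,33,95,137
B9,2,1.03,2.34,28,106,22,69,20,62,0,4,14,11,9,4,30,35,43,38,96,136
B9,3,1.03,2.49,33,98,28,77,17,53,46,86,13,13,10,15,34,38,40,31,96,128
B9,4,1.19,2.71,31,90,22,75,28,80,24,25,15,15,11,12,35,36,41,34,94,137
B10,1,0.76,1.86,19,99,22,71,12,38,39,125,10,10,4,12,34,31,35,22,99,223
B10,2,1.11,1.64,25,89,24,86,41,100,11,42,10,7,9,12,29,30,30,36,100,190
B10,3,0.6,1.64,19,95,21,78,48,109,13,20,10,6,9,6,35,29,41,36,100,207
B10,4,0.65,1.67,22,97,26,89,25,69,28,33,9,10,6,6,29,28,33,30,100,198
B11,1,1.73,1.57,24,84,28,85,15,53,35,60,10,10,11,10,31,25,38,35,99,136
B11,2,1.84,1.91,31,87,32,84,14,44,39,91,12,10,10,13,29,32,37,49,96,140
B11,3,1.25,1.99,31,91,30,81,14,47,42,100,12,12,10,26,28,31,38,19,99,145
B11,4,1.14,2.11,29,89,27,80,23,66,33,8,13,12,9,27,29,29,38,40,98,134
B12,1,2.33,1.72,26,96,24,79,28,28,23,32,10,10,6,19,27,28,36,22,94,178
B12,2,1.03,1.55,28,98,25,88,19,18,3,127,10,9,10,4,28,30,38,29,99,158
B12,3,1.19,1.46,29,90,22,88,12,34,35,117,9,10,6,9,30,29,37,21,98,144
B12,4,2.11,1.51,23,80,26,88,21,40,16,124,10,10,9,9,25,28,37,18,99,133
B13,1,1.25,1.63,17,84,21,72,20,28,26,37,10,10,6,10,28,28,37,46,95,146
B13,2,1.19,1.64,20,84,20,70,20,44,46,111,10,10,10,10,28,30,34,12,91,145
B13,3,1.08,1.50,16,69,23,61,14,53,31,22,7,6,10,13,26,29,39,23,92,151
B13,4,1.84,1.35,23,92,19,74,10,29,7,1,10,6,4,29,27,30,37,10,94,143
B14,1,2.28,2.60,18,93,24,86,20,43,37,112,15,19,12,9,42,29,37,31,88,147
B14,2,1.25,2.11,23,91,23,83,14,46,40,122,14,12,10,10,34,32,39,17,99,131
B14,3,1.25,2.18,23,93,19,83,16,38,34,100,14,12,10,12,33,33,42,24,100,134
B14,4,1.14,2.07,28,96,16,76,18,59,13,13,12,14,9,15,35,33,48,40,100,137
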