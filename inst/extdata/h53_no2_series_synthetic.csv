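time_h,replicate,excess29_nmol_per_L,excess30_nmol_per_L
0,R1,0,0
0,R2,0,0
0,R3,0,0
14,R1,2.0416666667,0.4083333333
14,R2,2.0416666667,0.4083333333
14,R3,2.0416666667,0.4083333333
24,R1,3.5,0.7
24,R2,3.5,0.7
24,R3,3.5,0.7
36,R1,5.25,1.05
36,R2,5.25,1.05
36,R3,5.25,1.05
48,R1,7,1.4
48,R2,7,1.4
48,R3,7,1.4
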