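time_h,replicate,excess29_nmol_per_L,excess30_nmol_per_L
0,R1,0,0
0,R2,0,0
0,R3,0,0
14,R1,2.7416666667,0
14,R2,2.7416666667,0
14,R3,2.7416666667,0
24,R1,4.7,0
24,R2,4.7,0
24,R3,4.7,0
36,R1,7.05,0
36,R2,7.05,0
36,R3,7.05,0
48,R1,9.4,0
48,R2,9.4,0
48,R3,9.4,0
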