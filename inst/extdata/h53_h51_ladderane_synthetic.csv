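well,date,area_ladderane3,area_ladderane5,area_C19_IS
H53,2015-11-01,20,15,10
H53,2014-12-01,14,21,10
H51,2015-11-01,0.6,0.4,10
H32,2015-11-01,0.03,0.04,10
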