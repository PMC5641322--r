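# Synthetic design mirroring a groundwater 15NH4+ incubation:
# 50 uM 15N-ammonium plus 5 uM unlabeled nitrite carrier.
water_volume_ml = 30
headspace_volume_ml = 8
temperature_c = 15
sampling_times_h = 0,14,24,36,48
replicates_per_time = 3
treatment = AMMONIUM_15N
added_15N_nitrite = 0
added_15N_ammonium = 50
added_14N_nitrite = 5
background_ammonium = 0
background_nitrite = 0
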