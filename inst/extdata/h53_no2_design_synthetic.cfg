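# Synthetic design mirroring a groundwater 15NO2- incubation:
# 5 uM 15N-nitrite tracer over a below-detection in-situ nitrite pool.
water_volume_ml = 30
headspace_volume_ml = 8
temperature_c = 15
sampling_times_h = 0,14,24,36,48
replicates_per_time = 3
treatment = NITRITE_15N
added_15N_nitrite = 5
added_15N_ammonium = 0
added_14N_nitrite = 0
background_ammonium = 12
background_nitrite = 0
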