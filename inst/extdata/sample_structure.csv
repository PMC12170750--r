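sex,n,age_min,age_max,age_mean,age_sd
female,18,62,92,80.1,5.86
male,14,60,93,76.6,10.5
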