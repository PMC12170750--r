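measurement,d_value,cutoff
MAXH,0.423,35.87
MAXT,0.220,17.55
MAXW,0.453,37.53
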