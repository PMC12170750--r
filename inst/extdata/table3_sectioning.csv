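measurement,d_value,cutoff
MAXH,0.019,40.20
MAXT,0.587,19.41
MAXW,0.785,41.28
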