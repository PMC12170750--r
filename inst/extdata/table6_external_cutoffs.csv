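source,measurement,cutoff
cavazzuti,MAXH,35.68
cavazzuti,MAXT,16.10
cavazzuti,MAXW,36.61
hlad,MAXH,36.30
hlad,MAXT,16.30
hlad,MAXW,38.10
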