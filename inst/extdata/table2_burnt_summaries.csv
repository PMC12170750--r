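measurement,sex,n,mean,sd,min,max
MAXH,female,18,33.33,4.53,27.11,42.93
MAXH,male,14,38.22,4.23,31.42,25.49
MAXT,female,18,17.01,1.96,14.48,21.82
MAXT,male,14,18.26,2.49,14.60,23.32
MAXW,female,18,34.90,4.43,28.33,44.96
MAXW,male,14,39.58,3.35,32.32,44.24
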