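measurement,sex,n,mean,sd,min,max
MAXH,female,18,37.95,2.98,30.17,33.48
MAXH,male,14,42.45,2.23,39.66,46.38
MAXT,female,18,18.83,1.82,16.08,22.00
MAXT,male,14,20.52,1.39,17.54,22.37
MAXW,female,18,38.99,3.26,44.39,45.95
MAXW,male,14,43.81,2.53,40.74,49.13
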