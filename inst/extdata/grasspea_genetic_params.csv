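trait,mean,min,max,gcv,pcv,h2,ga,ga_pct
DTM,119,115,122,0.8,0.92,0.76,1.72,1.44
BY,7.72,5.7,10.51,10.53,12.87,0.67,1.37,17.76
SY,1233.74,758.32,1740.25,10.42,13.69,0.58,201.72,16.35
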