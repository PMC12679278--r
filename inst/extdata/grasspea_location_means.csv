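code,location,DTM,BY,SY,BLPSI
L1,"FLRP, Amlaha",115,6.19,2000.71,2122.22
L2,"IGKV, Raipur",106,11.78,1003.36,NA
L3,"BCKV, Mohanpur",131,6.81,1112.64,1250.16
L4,"CAU, Imphal",126,6.09,818.25,950.01
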