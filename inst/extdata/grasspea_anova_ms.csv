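trait,source,df,ms,pct_contribution
DTM,Environment,3,13223.81,82.41
DTM,Genotype,63,794.30,4.95
DTM,Environment:Genotype,189,2028.26,12.64
BY,Environment,3,814.64,86.02
BY,Genotype,63,55.59,5.87
BY,Environment:Genotype,189,76.80,8.11
SY,Environment,3,28142885.31,78.34
SY,Genotype,63,2399725.22,6.68
SY,Environment:Genotype,189,5381419.73,14.98
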