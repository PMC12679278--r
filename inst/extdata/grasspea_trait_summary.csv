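stat,DTM,BY,SY
lsd_5pct,6.32,0.55,283.3
cv_pct,5.3,14.86,13.56
var_g,0.92,0.66,16536.58
var_ge,4.39,2.78,95370.46
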