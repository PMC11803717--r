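system,K_A,K_A_se
DOPC,245.81,9.85
DOPC:DSPG 65:35,192.7,10.8
DOPC:DSPA 65:35,201.5,7.0
DOPC:DSPS 65:35,203.1,3.6
DOPC:DHPC 65:35,220.5,3.8
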