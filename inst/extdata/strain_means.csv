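strain,reporter,mean_total,omega,n
wt,MglA,0.017,0.52,NA
wt,MglB,0.086,0.43,NA
wt,RomR,0.212,0.50,NA
dA,MglB,0.203,0.64,NA
dA,RomR,0.348,0.69,NA
dB,MglA,0.083,0.33,NA
dB,RomR,0.112,0.38,NA
dR,MglA,0.0002,NA,NA
dR,MglB,0.005,NA,NA
dAdB,RomR,0.108,0.41,NA
dAdR,MglB,0.011,0.57,NA
dBdR,MglA,0.006,NA,NA
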