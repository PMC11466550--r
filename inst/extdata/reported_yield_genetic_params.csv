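environment,sigma_g2,sigma_p2,heritability,mean_yield
BAM,2.59,2.78,0.93,5.08
DAK,2.10,2.50,0.84,5.36
FN,1.74,2.35,0.74,4.50
NEB1,0.88,0.96,0.91,5.63
NEB2,1.21,1.42,0.85,5.21
PD,0.74,0.81,0.91,2.29
SG,2.90,3.11,0.93,7.06
TM,1.15,1.26,0.91,9.92
YEN,3.75,3.95,0.95,5.01
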