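name,full_name
NEB1,Neboum 1
NEB2,Neboum 2
TM,Toumousseni
BAM,Bama
SG,Soungalodaga
FN,Fina
DAK,Dakoro
YEN,Yendere
PD,Poundou
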