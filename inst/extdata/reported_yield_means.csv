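environment,genotype,yield_t_ha,letters
NEB1,SD1,6.992,c
NEB1,SD2,5.344,ab
NEB1,SD3,5.027,ab
NEB1,SD4,6.221,bc
NEB1,SD5,6.652,c
NEB1,SD6,5.987,bc
NEB1,SD7,4.237,a
NEB1,SD9,4.626,a
NEB2,SD1,6.524,b
NEB2,SD2,6.063,b
NEB2,SD3,5.724,ab
NEB2,SD4,5.644,ab
NEB2,SD5,6.283,b
NEB2,SD6,3.853,a
NEB2,SD7,3.777,a
NEB2,SD9,3.797,a
TM,SD1,5.794,c
TM,SD2,5.982,c
TM,SD3,4.324,b
TM,SD4,5.816,c
TM,SD5,5.854,c
TM,SD6,4.766,bc
TM,SD7,3.893,ab
TM,SD9,2.960,a
BAM,SD1,9.054,d
BAM,SD2,6.488,b
BAM,SD3,5.521,b
BAM,SD4,7.249,bc
BAM,SD5,6.451,b
BAM,SD6,8.272,cd
BAM,SD7,5.543,b
BAM,SD8,3.774,a
SG,SD1,8.714,d
SG,SD2,6.081,bc
SG,SD3,7.683,cd
SG,SD4,7.734,cd
SG,SD5,7.462,cd
SG,SD6,9.385,d
SG,SD7,4.191,a
SG,SD9,5.227,ab
FN,SD1,6.522,c
FN,SD2,4.315,abc
FN,SD3,5.648,bc
FN,SD4,6.480,bc
FN,SD5,4.333,abc
FN,SD6,5.636,bc
FN,SD7,2.004,a
FN,SD9,2.786,ab
DAK,SD1,7.788,c
DAK,SD2,5.868,bc
DAK,SD3,4.900,b
DAK,SD4,6.480,bc
DAK,SD5,5.557,bc
DAK,SD6,5.636,bc
DAK,SD8,2.528,a
DAK,SD9,4.137,ab
YEN,SD1,7.971,d
YEN,SD2,4.134,ab
YEN,SD3,6.063,c
YEN,SD4,4.775,b
YEN,SD5,7.543,d
YEN,SD6,3.217,ab
YEN,SD7,3.681,ab
YEN,SD9,2.675,a
PD,SD1,4.016,d
PD,SD2,2.096,abc
PD,SD3,2.932,c
PD,SD4,1.591,ab
PD,SD5,2.584,bc
PD,SD6,1.829,abc
PD,SD7,1.060,a
PD,SD9,2.241,bc
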