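code,designation,material_class,origin
SD1,WE3205,single_cross,Kenya
SD2,WE4207,single_cross,South Africa
SD3,SNK2778,double_cross,Nigeria/Zambia
SD4,DK920,single_cross,Nigeria
SD5,DK234,single_cross,Nigeria
SD6,DK818,single_cross,Nigeria
SD7,SR21,national_hybrid,Burkina Faso
SD8,BONDOFA,national_hybrid,Burkina Faso
SD9,KOMSAYA,composite,Burkina Faso
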