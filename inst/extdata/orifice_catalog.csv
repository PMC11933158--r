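label,shape,h_mm,w_mm,area_mm2
circle-S,circle,4.7,NA,17.1
circle-M,circle,8.7,NA,58.8
circle-L,circle,12.2,NA,116.7
slit-S,slit,3.3,11.1,27.0
slit-M,slit,4.5,14.0,44.8
slit-L,slit,7.3,22.9,115.1
drop-S,drop,4.3,9.7,27.1
drop-M,drop,6.5,13.7,52.1
drop-L,drop,9.0,19.8,108.4
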