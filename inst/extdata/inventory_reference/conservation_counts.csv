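listing,category,count
iucn,CR,12
iucn,EN,113
iucn,VU,124
iucn,NT,27
iucn,LC,643
iucn,DD,21
iucn,LR/cd,3
iucn,LR/nt,4
iucn,LR/lc,17
nom059,P,13
nom059,A,31
nom059,Pr,29
cites,I,3
cites,II,93
cites,II/NC,1
cites,III,1
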