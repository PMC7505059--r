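key,value
n_species,2885
n_genera,612
n_families,128
n_endemic,1264
n_useful,674
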