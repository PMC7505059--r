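genus,family,species,endemic_species
Quercus,Fagaceae,133,84
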