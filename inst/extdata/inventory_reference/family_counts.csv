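family,species,endemic_species
Fabaceae,513,229
Rubiaceae,210,91
Fagaceae,134,84
Lauraceae,131,57
Malvaceae,112,59
Myrtaceae,92,24
Burseraceae,90,76
Euphorbiaceae,74,39
Rosaceae,60,31
Cactaceae,59,53
Salicaceae,57,16
Pinaceae,55,20
Asparagaceae,53,37
Rutaceae,53,26
Annonaceae,51,22
Moraceae,43,0
Sapotaceae,42,0
Anacardiaceae,41,25
Arecaceae,41,14
Asteraceae,41,14
Boraginaceae,41,14
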