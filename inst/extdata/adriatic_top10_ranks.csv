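species_id,rank_cig,rank_lg,rank_lig
Lentidium mediterraneum,1,3,1
Chamelea gallina,2,12,5
Donax semistriatus,3,,7
Spisula subtruncata,4,1,2
Bittium reticulatum,5,5,8
Varicorbula gibba,6,15,16
Ecrobia gr. ventrosa,7,6,6
Bela formica,8,23,10
Peronidia albicans,9,,14
Tritia varicosa,10,41,32
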