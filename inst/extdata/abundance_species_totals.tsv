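group	taxon	species
typeIIb	animals	0
typeIIb	fungi	285
typeIIb	plants	4
typeIIb	bacteria	1041
typeIIb	archaea	1
BVMO	animals	6
BVMO	fungi	549
BVMO	plants	2
BVMO	bacteria	1656
BVMO	archaea	9
FMO_like_plant	animals	409
FMO_like_plant	fungi	244
FMO_like_plant	plants	106
FMO_like_plant	bacteria	1306
FMO_like_plant	archaea	0
FMO_like_bacteria	animals	187
FMO_like_bacteria	fungi	433
FMO_like_bacteria	plants	114
FMO_like_bacteria	bacteria	837
FMO_like_bacteria	archaea	0
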