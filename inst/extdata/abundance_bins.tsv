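group	taxon	bin	homologs
typeIIb	animals	strong	0
typeIIb	animals	mid	0
typeIIb	animals	weak	0
typeIIb	fungi	strong	419
typeIIb	fungi	mid	80
typeIIb	fungi	weak	8
typeIIb	plants	strong	4
typeIIb	plants	mid	0
typeIIb	plants	weak	3
typeIIb	bacteria	strong	1387
typeIIb	bacteria	mid	2
typeIIb	bacteria	weak	19
typeIIb	archaea	strong	1
typeIIb	archaea	mid	0
typeIIb	archaea	weak	0
BVMO	animals	strong	8
BVMO	animals	mid	4
BVMO	animals	weak	4
BVMO	fungi	strong	918
BVMO	fungi	mid	3475
BVMO	fungi	weak	1198
BVMO	plants	strong	1
BVMO	plants	mid	2
BVMO	plants	weak	1
BVMO	bacteria	strong	3155
BVMO	bacteria	mid	1090
BVMO	bacteria	weak	1605
BVMO	archaea	strong	1
BVMO	archaea	mid	9
BVMO	archaea	weak	1
FMO_like_plant	animals	strong	0
FMO_like_plant	animals	mid	0
FMO_like_plant	animals	weak	2486
FMO_like_plant	fungi	strong	0
FMO_like_plant	fungi	mid	0
FMO_like_plant	fungi	weak	417
FMO_like_plant	plants	strong	512
FMO_like_plant	plants	mid	16
FMO_like_plant	plants	weak	302
FMO_like_plant	bacteria	strong	0
FMO_like_plant	bacteria	mid	4
FMO_like_plant	bacteria	weak	2052
FMO_like_plant	archaea	strong	0
FMO_like_plant	archaea	mid	0
FMO_like_plant	archaea	weak	0
FMO_like_bacteria	animals	strong	0
FMO_like_bacteria	animals	mid	2
FMO_like_bacteria	animals	weak	2917
FMO_like_bacteria	fungi	strong	0
FMO_like_bacteria	fungi	mid	0
FMO_like_bacteria	fungi	weak	1305
FMO_like_bacteria	plants	strong	0
FMO_like_bacteria	plants	mid	612
FMO_like_bacteria	plants	weak	993
FMO_like_bacteria	bacteria	strong	329
FMO_like_bacteria	bacteria	mid	537
FMO_like_bacteria	bacteria	weak	8660
FMO_like_bacteria	archaea	strong	0
FMO_like_bacteria	archaea	mid	0
FMO_like_bacteria	archaea	weak	0
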