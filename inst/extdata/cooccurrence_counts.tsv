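species	taxon	n_typeIIb	n_yucca
TVSH_201823_Bituminaria_bituminosa	Core Eudicots	1	2
WWQZ_211706_Medinilla_magnifica	Core Eudicots	1	1
OCWZ_200432_Dioscorea_villosa	Monocots	1	2
AFPO_201018_Blechnum_spicant	Leptosporangiate monilophytes	4	1
BMJR_200209_Adiantum_tenerum	Leptosporangiate monilophytes	2	2
DCDT_207190_Cheilanthes_arizonica	Leptosporangiate monilophytes	3	1
FLTD_200266_Pteris_ensigormis	Leptosporangiate monilophytes	1	2
GANB_201380_Cyathea_spinulosa	Leptosporangiate monilophytes	4	1
KIIX_201108_Pilularia_globulifera	Leptosporangiate monilophytes	2	1
KJZG_200972_Asplenium_platyneuron	Leptosporangiate monilophytes	5	1
NDUV_201591_Vittaria_appalachiana	Leptosporangiate monilophytes	1	2
NOKI_201577_Lindsaea_linearis	Leptosporangiate monilophytes	5	1
PNZO_215202_Culcita_macrocarpa	Leptosporangiate monilophytes	1	1
RICC_200988_Cystopteris_reevesiana	Leptosporangiate monilophytes	3	1
UFJN_208949_Diplazium_wichurae	Leptosporangiate monilophytes	3	1
UOMY_200602_Osmunda_sp	Leptosporangiate monilophytes	1	1
WQML_200900_Cryptogramma_acrostichoides	Leptosporangiate monilophytes	1	2
YLJA_207326_Polypodium_amorphum	Leptosporangiate monilophytes	2	1
RXRQ_201835_Phaeoceros_carolinianus	Hornworts	3	1
TCBC_200001_Megaceros_vincentianus	Hornworts	1	1
HMHL_201008_Marchantia_paleacea	Liverworts	2	1
ILBQ_200700_Conocephalum_conicum	Liverworts	2	1
TXVB_207470_Lunularia_cruciata	Liverworts	3	1
RCBT_Sphagnum_palustre	Mosses	1	1
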