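taxon	n_species_sampled
Eudicots	596
Monocots	104
Conifers	73
Cycadales	4
Leptosporangiate monilophytes	65
Eusporangiate monilophytes	12
Lycophytes	22
Hornworts	9
Liverworts	28
Bryophyta	41
Zygnemophyceae	5
Coleochaetophyceae	3
Charophyceae	1
Mesostigmatophyceae	1
Chlorokybophyceae	1
Klebsormidiophyceae	2
Green algae	152
Red algae	28
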