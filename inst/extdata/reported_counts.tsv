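quantity	group	count
synthase_language	HAQ	3359
synthase_language	DSF	3096
synthase_language	CAI-1	2376
synthase_language	AHL	2006
synthase_language	indole	1312
synthase_language	AI-2	1180
synthase_language	DAR	1110
synthase_language	AIP	11
receptor_total	all	178856
species_total	all	4228
qsb_species	all	3878
receptor_genes	gram_negative	77
receptor_genes	gram_positive	40
synthase_genes	gram_negative	75
reannotated	functional	345
reannotated	no_qs_function	92
reannotated	vague	113
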