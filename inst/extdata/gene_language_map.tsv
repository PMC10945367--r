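gene_name	role	language	low_confidence
luxI	synthase	AHL	FALSE
lasI	synthase	AHL	FALSE
rhlI	synthase	AHL	FALSE
esaI	synthase	AHL	FALSE
luxR	receptor	AHL	FALSE
lasR	receptor	AHL	FALSE
rhlR	receptor	AHL	FALSE
luxS	synthase	AI-2	FALSE
luxP	receptor	AI-2	FALSE
luxQ	receptor	AI-2	FALSE
lsrB	receptor	AI-2	FALSE
cqsA	synthase	CAI-1	FALSE
cqsS	receptor	CAI-1	FALSE
darA	synthase	DAR	FALSE
darB	synthase	DAR	FALSE
pqsA	synthase	HAQ	FALSE
pqsB	synthase	HAQ	FALSE
pqsC	synthase	HAQ	FALSE
pqsD	synthase	HAQ	FALSE
pqsH	synthase	HAQ	FALSE
pqsR	receptor	HAQ	FALSE
rpfF	synthase	DSF	FALSE
rpfC	receptor	DSF	FALSE
rpfG	receptor	DSF	FALSE
tnaA	synthase	indole	FALSE
agrB	synthase	AIP	TRUE
agrD	synthase	AIP	TRUE
agrC	receptor	AIP	FALSE
agrA	receptor	AIP	FALSE
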