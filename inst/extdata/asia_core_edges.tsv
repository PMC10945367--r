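# Documentation fixture (literature data, not recomputed by this package):
# the published co-occurrence edges among connected Asian activated-sludge
# core species, given by species acronym.
species_a	species_b	acronym_a	acronym_b
Thauera humireducens	Denitratisoma oestradiolicum	TH	DO
Romboutsia timonensis	Allochromatium palmeri	RT	AP
Allochromatium palmeri	Flavilitoribacter nigricans	AP	FN
Lacibacter nakdongensis	Acidibacter ferrireducens	LN	AF
Usitatibacter palustris	Acidibacter ferrireducens	UP	AF
Usitatibacter palustris	Lacibacter nakdongensis	UP	LN
Usitatibacter palustris	Flavilitoribacter nigricans	UP	FN
Methyloglobulus morosus	Woodsholea maritima	MM	WM
Methyloglobulus morosus	Tepidiforma flava	MM	TF
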