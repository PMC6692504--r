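clade	n_species	second_locus_location	source_system
Blastobotrys_proliferans	1	telomere	HET
Kuraishia_molischiana	1	telomere	HET
Yamadazyma_nakazawae_philogaea	2	telomere	HET
Wickerhamia_fluorescens	1	telomere	HET
Saccharomycopsis_capsularis	1	telomere	HET
Lipomyces_oligophaga_suomiensis	2	telomere	PHC
Kazachstania_rosinii	1	telomere	3LOC
Nadsonia_fulvescens_elongata	1	telomere	HET
Kazachstania_africana	1	subtelomeric_rearrangement	3LOC
Peterozyma_xylosa_toletana	2	rdna	HET
Lipomyces_japonicus	1	none	PHC
Ambrosiozyma_ambrosiae_philentoma	2	none	HET
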