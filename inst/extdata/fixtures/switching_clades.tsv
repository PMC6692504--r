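clade	system	n_species	provisional	major_clade
Saccharomycetaceae_3LOC	3LOC	66	FALSE	Saccharomycetaceae
Pachysolen_tannophilus	FF1	1	FALSE	CUG-Ala
Ascoidea_rubescens	FF1	1	FALSE	CUG-Ser2
Ogataea_polymorpha_clade	FF1	12	FALSE	Pichiaceae
Ogataea_trehalophila_methanolica	FF1	2	FALSE	Pichiaceae
Ogataea_pilisensis	FF1	1	FALSE	Pichiaceae
Cyberlindnera_saturnus_clade	FF1	3	FALSE	Phaffomycetaceae
Starmera_quercuum	FF1	1	FALSE	Phaffomycetaceae
Kregervanrija_fluxuum_delftensis	FF1	2	FALSE	Pichiaceae
Komagataella_clade	FF2	3	FALSE	Pichiaceae
Saturnispora_zaruensis_clade	FF2	4	FALSE	Pichiaceae
Wickerhamomyces_canadensis	FF2	1	TRUE	Phaffomycetaceae
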