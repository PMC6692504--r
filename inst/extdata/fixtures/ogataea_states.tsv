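species	category
Ogataea_methylivora	HET
Ogataea_ramenticola	HET
Candida_succiphila	HET
Ogataea_naganishii	PHC
Ogataea_polymorpha	FF1
Ogataea_parapolymorpha	FF1
Ogataea_nonfermentans	FF1
Ogataea_philodendri	FF1
Ogataea_kodamae	FF1
Ogataea_minuta	FF1
Ogataea_henricii	FF1
Ogataea_pini	FF1
Ogataea_glucozyma	FF1
Ogataea_zsoltii	FF1
Ogataea_trehaloabstinens	FF1
Ogataea_populialbae	FF1
Ogataea_trehalophila	FF1
Ogataea_methanolica	FF1
Candida_arabinofermentans	HET
Ogataea_pilisensis	FF1
Ogataea_nitratoaversa	HET
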