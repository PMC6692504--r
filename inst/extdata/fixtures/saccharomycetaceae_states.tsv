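species	category
Saccharomyces_cerevisiae	3LOC
Saccharomyces_paradoxus	3LOC
Saccharomyces_mikatae	3LOC
Saccharomyces_kudriavzevii	3LOC
Saccharomyces_arboricola	3LOC
Saccharomyces_eubayanus	3LOC
Saccharomyces_uvarum	3LOC
Saccharomyces_jurei	3LOC
Nakaseomyces_bacillisporus	3LOC
Candida_nivariensis	3LOC
Candida_bracarensis	3LOC
Candida_glabrata	3LOC
Nakaseomyces_delphensis	3LOC
Candida_castellii	3LOC
Kazachstania_sp_A	3LOC
Kazachstania_sp_B	3LOC
Kazachstania_sp_C	3LOC
Kazachstania_sp_D	3LOC
Kazachstania_sp_E	3LOC
Kazachstania_sp_F	3LOC
Kazachstania_sp_G	3LOC
Kazachstania_sp_H	3LOC
Kazachstania_sp_I	3LOC
Kazachstania_sp_J	3LOC
Kazachstania_sp_K	3LOC
Kazachstania_sp_L	3LOC
Kazachstania_sp_M	3LOC
Kazachstania_africana	PHN
Kazachstania_rosinii	PHN
Kazachstania_yakushimaensis	HET
Kazachstania_transvaalensis	HET
Naumovozyma_castellii	3LOC
Naumovozyma_dairenensis	3LOC
Naumovozyma_sp_A	3LOC
Tetrapisispora_fleetii	3LOC
Tetrapisispora_phaffii	3LOC
Tetrapisispora_blattae	3LOC
Tetrapisispora_iriomotensis	3LOC
Tetrapisispora_namnaonensis	3LOC
Vanderwaltozyma_polyspora	3LOC
Vanderwaltozyma_sp_A	3LOC
Yueomyces_sinensis	3LOC
Torulaspora_delbrueckii	3LOC
Torulaspora_pretoriensis	3LOC
Torulaspora_franciscae	3LOC
Torulaspora_microellipsoides	3LOC
Torulaspora_globosa	3LOC
Zygotorulaspora_mrakii	3LOC
Zygotorulaspora_florentina	3LOC
Zygosaccharomyces_rouxii	3LOC
Zygosaccharomyces_bailii	3LOC
Zygosaccharomyces_bisporus	3LOC
Zygosaccharomyces_kombuchaensis	3LOC
Zygosaccharomyces_sp_A	3LOC
Lachancea_thermotolerans	3LOC
Lachancea_waltii	3LOC
Lachancea_fantastica	3LOC
Lachancea_quebecensis	3LOC
Lachancea_lanzarotensis	3LOC
Lachancea_fermentati	3LOC
Lachancea_cidri	3LOC
Lachancea_kluyveri	HET
Eremothecium_cymbalariae	3LOC
Eremothecium_gossypii	3LOC
Eremothecium_coryli	3LOC
Ashbya_aceri	3LOC
Kluyveromyces_lactis	3LOC
Kluyveromyces_marxianus	3LOC
Kluyveromyces_aestuarii	3LOC
Kluyveromyces_dobzhanskii	3LOC
Kluyveromyces_wickerhamii	3LOC
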