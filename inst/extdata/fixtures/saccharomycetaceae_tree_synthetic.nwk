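(((((Saccharomyces_cerevisiae,(Saccharomyces_paradoxus,(Saccharomyces_mikatae,(Saccharomyces_kudriavzevii,(Saccharomyces_arboricola,(Saccharomyces_eubayanus,(Saccharomyces_uvarum,Saccharomyces_jurei))))))),(Nakaseomyces_bacillisporus,((Candida_nivariensis,Candida_bracarensis),((Candida_glabrata,Nakaseomyces_delphensis),Candida_castellii)))),((Kazachstania_sp_A,(Kazachstania_africana,(Kazachstania_sp_B,(Kazachstania_sp_C,(Kazachstania_rosinii,(Kazachstania_sp_D,(Kazachstania_sp_E,((Kazachstania_yakushimaensis,Kazachstania_transvaalensis),(Kazachstania_sp_F,(Kazachstania_sp_G,(Kazachstania_sp_H,(Kazachstania_sp_I,(Kazachstania_sp_J,(Kazachstania_sp_K,(Kazachstania_sp_L,Kazachstania_sp_M))))))))))))))),((Naumovozyma_castellii,(Naumovozyma_dairenensis,Naumovozyma_sp_A)),((Tetrapisispora_fleetii,(Tetrapisispora_phaffii,(Tetrapisispora_blattae,(Tetrapisispora_iriomotensis,Tetrapisispora_namnaonensis)))),((Vanderwaltozyma_polyspora,Vanderwaltozyma_sp_A),Yueomyces_sinensis))))),((Torulaspora_delbrueckii,(Torulaspora_pretoriensis,(Torulaspora_franciscae,(Torulaspora_microellipsoides,Torulaspora_globosa)))),((Zygotorulaspora_mrakii,Zygotorulaspora_florentina),(Zygosaccharomyces_rouxii,(Zygosaccharomyces_bailii,(Zygosaccharomyces_bisporus,(Zygosaccharomyces_kombuchaensis,Zygosaccharomyces_sp_A))))))),((Lachancea_thermotolerans,(Lachancea_waltii,(Lachancea_kluyveri,(Lachancea_fantastica,(Lachancea_quebecensis,(Lachancea_lanzarotensis,(Lachancea_fermentati,Lachancea_cidri))))))),((Eremothecium_cymbalariae,(Eremothecium_gossypii,Eremothecium_coryli)),(Ashbya_aceri,(Kluyveromyces_lactis,(Kluyveromyces_marxianus,(Kluyveromyces_aestuarii,(Kluyveromyces_dobzhanskii,Kluyveromyces_wickerhamii))))))));
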