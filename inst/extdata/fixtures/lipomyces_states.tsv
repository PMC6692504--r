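species	category
Lipomyces_starkeyi	PHC
Lipomyces_arxii	PHC
Lipomyces_mesembrius	PHC
Lipomyces_kononenkoae	PHC
Lipomyces_lipofer	PHC
Lipomyces_doorenjongii	HET
Lipomyces_japonicus	PHN
Lipomyces_suomiensis	PHN
Lipomyces_oligophaga	PHN
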