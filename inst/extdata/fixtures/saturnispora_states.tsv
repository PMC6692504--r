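species	category
Saturnispora_zaruensis	FF2
Saturnispora_hagleri	FF2
Saturnispora_dispora	FF2
Saturnispora_serradocipensis	FF2
Saturnispora_mendoncae	HET
Saturnispora_sp_A	HET
Saturnispora_sp_B	HET
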