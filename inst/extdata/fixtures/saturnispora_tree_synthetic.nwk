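(((Saturnispora_zaruensis,Saturnispora_hagleri),(Saturnispora_dispora,Saturnispora_serradocipensis)),(Saturnispora_mendoncae,(Saturnispora_sp_A,Saturnispora_sp_B)));
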