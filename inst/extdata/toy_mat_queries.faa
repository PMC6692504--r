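>MATa1|mat_core|toy
MVFYIDDVVHYTPSQCFKAHIWQYTFGWMSLAEPPRQRTTRDLYCQVYSMDRSDAPKGFYIYKFSPEHAKMKMETDGIKN
ALPQEYAVWGHSFNMKDQEQWDVPMDLKNSIFEYTWMDGC
>MATa2|mat_core|toy
MCDLFIAAMAILDYDGNWCMEEKMIVWKQIFTESIMSISVEVHVSFFLVHGAAGYTSMVRACPDHYMRHPVAYIFGNNSR
YPEMLRCGHMHISNCNFYKCEHYEGHKNKKMRRTCDRCSC
>MATalpha1|mat_core|toy
MRHKHWISTKMWTHSAKRICRQNRYPRDENRNEPWFVVWYQGANWVESVEMGAFESMLEVFASVHWQNDNFYREDIQHPQ
EEGEWTYSWCRADPETVECCLTLMFSTERMASWKYKCQDE
>MATalpha2|mat_core|toy
MVVEHTMECWGAMRAIYVPTQSFYCLNEAKLTWCPMTMNQILGYGSWDRAWTKWFDIGYRLFIFSQVAHVEKPLCSEIHV
TQIWIDEPRLSEVPWQRIYEGCKTHNVLLFTRDQFYFFVI
>SLA2|neighbor|toy
MENWTWYDDQVEMAVRMLMTVVCAQSVTRNYIFVLPQVCVADGQPVVYNFRRLNHCGNWDIAAPTQCHSGVRTPVIIQCW
FRGPAPNCVWIPYKCALWPFEWAHPIDYDMCSAQWFHWWGAGDRKDLTLHILYVRYQYEMLTLLKVPNYTCNSCMTILID
>DIC1|neighbor|toy
MIYFIHAVGSGMIPQNVQHTWHNNPLYTCQLVQKCLMGVETTENQEEWRDAYTWHSWWNDHALYHEPQGYIFEKAFLLMN
ASGVVWYNVTPRPGVTDGENQVRAYVREQYTQRILLMHIWPIPHWCEAELQMVLCDAGACDIFYKHWIKSHQEKPFDSQA
>APN2|neighbor|toy
MAWKHQLITLCHEWSTPEIEPRKDGVLCHIHKHQTEHTRCVTLYLETHDKVEFCYKEYMLAIICRWMLMVCGMFESKSWQ
RCKIMFVQREQLTEIKPQIPGDTSMEYMDTNEIVYFTPAKACMQVVTFFVQKHTSDICSGGMDQSNGAMVMTARVNFKIP
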