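gene	chromosome	forward	reverse
W07G4.4	V	GCAATCGCTCCAGCCGTTAACAAT	TCGTCCAGATGGAACGACAGATGA
act-1	V	TGCAGAAGGAAATCACCGCTCTTG	AAGCACTTGCGGTGAACGATGGAT
apl-1	X	ACGACGACGATGAGGATGATGCTT	TGAACTTCTCGGCTCCCTTTGGAT
aco-1	X	CAAGATCAACCCAGTATGCCCAGT	ACCTGATGGACGATTCCAGATCCT
ajm-1	X	TCGTCTTGATGAGATGGAACGCGA	AAGTTCTGCGTTACGTTGGGCTTG
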