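# NIH-style reactive/excluded functionality catalog - curated snapshot
# subset, hand-assembled for this package; not the complete published
# catalog. Format: SMARTS<TAB>label.
[CX3](=O)[Cl,Br,I]	acyl_halide
[CX3H1]=O	aldehyde
C1OC1	epoxide
C1NC1	aziridine
[NX2]=C=O	isocyanate
[NX2]=C=S	isothiocyanate
[SX2H]	thiol
[CX3]=[CX3][CX3]=O	michael_acceptor
[CX4H2][Cl,Br,I]	primary_alkyl_halide
[CX3](=O)O[CX3]=O	anhydride
[OX2][OX2]	peroxide
[NX3][NX3]	hydrazine
[NX2]=[N+]=[N-]	azide
[CX3]=[N+]=[N-]	diazo
[NX2]=O	nitroso
[CX3](=O)[SX2]	thioester
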