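# Unwanted-substructure catalog (Brenk-style liabilities) - curated snapshot
# subset, hand-assembled for this package; not the complete published
# catalog. Format: SMARTS<TAB>label.
[N+](=O)[O-]	nitro_group
S(=O)(=O)[OH]	sulfonic_acid
S(=O)(=O)[Cl,Br]	sulfonyl_halide
[NX4+]	quaternary_nitrogen
[CX3]=[NX2H]	unsubstituted_imine
[CX3]=[NX2][OH]	oxime
[NX3]C#N	cyanamide
[NX3][CX3](=S)[NX3]	thiourea
[CX3](=S)[NX3]	thioamide
[PX3]	phosphine
[SX2][SX2]	disulfide
C=CC=CC=C	polyene
O=C1CC[NX3]1	beta_lactam
[CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2][CX4H2]	long_aliphatic_chain
[Si]	silicon
[B]	boron_nonring
[CX3](=O)O[CX3](=O)	reactive_diacyl
[SX3](=O)[Cl,Br]	sulfinyl_halide
[CX4]([Cl,Br,I])([Cl,Br,I])	geminal_dihalide
[NX3][OH]	hydroxylamine
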