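# PAINS (pan-assay interference) substructure catalog - curated snapshot
# subset, hand-assembled for this package; not the complete published
# catalog. Format: SMARTS<TAB>label. Lines starting with # are comments.
O=C1CSC(=S)N1	rhodanine
S=C1[NX3]C(=O)C(=[CX3])S1	ene_rhodanine
O=C1C=CC(=O)C=C1	para_quinone
O=C1C(=O)C=CC=C1	ortho_quinone
[OH]c1ccccc1[OH]	catechol
[OH]c1ccc([OH])cc1	hydroquinone
[#6]=[NX2][NX3]	hydrazone
c[NX2]=[NX2]c	azo_aromatic
O=C1[NX3]C(=O)[NX3]C(=O)C1=[CX3]	ene_barbiturate
[NX3][CX3]=[CX3][CX3]=O	enamine_michael
c1ccc2c(c1)C(=O)c1ccccc1C2=O	anthraquinone
[OH]c1cccc2cccnc12	hydroxyquinoline
[SX2]c1nc2ccccc2s1	thioether_benzothiazole
O=C1C=C[CX4][NX3]1	unsat_lactam
[NX3]c1ccc([NX3])cc1	phenylenediamine
O=[CX3]c1ccc([OH])cc1	hydroxybenzaldehyde
c1ccc(cc1)[CX3]=[CX3][CX3]=O	chalcone
[OH]c1ccccc1[CX3]=[NX2]	salicylaldimine
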