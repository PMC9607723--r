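label	filename	attachment_atom	smiles
H	H.sdf	1	[H][H]
methyl	methyl.sdf	1	C
ethyl	ethyl.sdf	1	CC
propyl	propyl.sdf	1	CCC
isopropyl	isopropyl.sdf	1	C(C)C
tert-butyl	tert_butyl.sdf	1	C(C)(C)C
cyclopropyl	cyclopropyl.sdf	1	C1CC1
cyclohexyl	cyclohexyl.sdf	1	C1CCCCC1
phenyl	phenyl.sdf	1	c1ccccc1
benzyl	benzyl.sdf	1	Cc1ccccc1
hydroxy	hydroxy.sdf	1	O
methoxy	methoxy.sdf	1	OC
ethoxy	ethoxy.sdf	1	OCC
propoxy	propoxy.sdf	1	OCCC
amino	amino.sdf	1	N
methylamino	methylamino.sdf	1	NC
dimethylamino	dimethylamino.sdf	1	N(C)C
fluoro	fluoro.sdf	1	F
chloro	chloro.sdf	1	Cl
bromo	bromo.sdf	1	Br
cyano	cyano.sdf	1	C#N
trifluoromethyl	trifluoromethyl.sdf	1	C(F)(F)F
acetyl	acetyl.sdf	1	C(C)=O
carbamoyl	carbamoyl.sdf	1	C(N)=O
methylsulfonyl	methylsulfonyl.sdf	1	S(C)(=O)=O
pyridin-4-yl	pyridin_4_yl.sdf	1	c1ccncc1
uracil-1-yl	uracil_1_yl.sdf	1	N1C=CC(=O)NC1=O
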