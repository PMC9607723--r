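hydroxy
  growkit          3D

  3  2  0  0  0  0  0  0  0  0999 V2000
    0.9008    0.0616    0.0095 O   0  0  0  0  0  0  0  0  0  0  0  0
    1.8687    0.0392   -0.0312 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6220   -0.3863   -0.8033 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
M  END
$$$$
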