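chloro
  growkit          3D

  2  1  0  0  0  0  0  0  0  0999 V2000
    0.9909    0.0498    0.0814 Cl  0  0  0  0  0  0  0  0  0  0  0  0
    2.2967    0.0498    0.0814 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
$$$$
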