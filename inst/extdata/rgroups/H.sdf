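H
  growkit          3D

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.2171    0.0201    0.0674 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.9251    0.0201    0.0674 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
$$$$
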