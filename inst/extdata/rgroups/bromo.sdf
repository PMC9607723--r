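bromo
  growkit          3D

  2  1  0  0  0  0  0  0  0  0999 V2000
    1.0064    0.0362    0.0856 Br  0  0  0  0  0  0  0  0  0  0  0  0
    2.4573    0.0362    0.0856 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
$$$$
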