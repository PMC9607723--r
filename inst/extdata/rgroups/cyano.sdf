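cyano
  growkit          3D

  3  2  0  0  0  0  0  0  0  0999 V2000
    1.1155    0.0799    0.0147 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.2755    0.0799    0.0147 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.0505    0.0799    0.0147 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  3  0  0  0  0
  1  3  1  0  0  0  0
M  END
$$$$
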