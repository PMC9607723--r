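propyl
  growkit          3D

 11 10  0  0  0  0  0  0  0  0999 V2000
    0.9217   -0.0467   -0.0306 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4408   -0.0747   -0.0269 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9735   -1.4870    0.1448 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5611    0.9793   -0.1556 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5204   -0.4359    0.9105 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.5207   -0.6504   -0.8510 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8157    0.5584    0.7851 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8159    0.3452   -0.9670 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6353   -1.9209    1.0914 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0679   -1.4830    0.1445 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6355   -2.1350   -0.6701 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
  1  6  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  1  0  0  0  0
  2  8  1  0  0  0  0
  3  9  1  0  0  0  0
  3 10  1  0  0  0  0
  3 11  1  0  0  0  0
M  END
$$$$
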