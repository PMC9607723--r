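methyl
  growkit          3D

  5  4  0  0  0  0  0  0  0  0999 V2000
    1.0110    0.0441   -0.0891 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1032    0.0441   -0.0891 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6469    1.0350    0.1913 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6469   -0.6941    0.6288 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6469   -0.2084   -1.0873 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
M  END
$$$$
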