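dimethylamino
  growkit          3D

 10  9  0  0  0  0  0  0  0  0999 V2000
    1.0234    0.0381    0.0987 N   0  0  0  0  0  0  0  0  0  0  0  0
    0.5213   -0.9735    1.0188 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.4800    0.0516    0.0875 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6814    0.9542    0.3877 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8485   -1.9752    0.7220 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5732   -0.9674    1.0064 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8480   -0.7793    2.0457 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8818   -0.9111   -0.2448 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8866    0.2877    1.0763 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8327    0.8151   -0.6130 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  3  8  1  0  0  0  0
  3  9  1  0  0  0  0
  3 10  1  0  0  0  0
M  END
$$$$
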