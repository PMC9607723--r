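ethyl
  growkit          3D

  8  7  0  0  0  0  0  0  0  0999 V2000
    1.0870   -0.0005    0.0557 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5991   -0.0005    0.0557 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7028   -0.6825   -0.7086 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7027    1.0024   -0.1528 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7027   -0.3214    1.0285 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9834    0.3204   -0.9171 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9834   -1.0034    0.2642 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9834    0.6815    0.8200 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  2  8  1  0  0  0  0
M  END
$$$$
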