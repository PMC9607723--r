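methoxy
  growkit          3D

  6  5  0  0  0  0  0  0  0  0999 V2000
    1.0010    0.0927    0.0228 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4167    0.1020    0.0175 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7081    0.8943   -0.4431 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7798   -0.7890    0.5353 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7782    0.9941    0.5348 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7782    0.0940   -1.0137 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  2  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
M  END
$$$$
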