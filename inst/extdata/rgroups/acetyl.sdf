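acetyl
  growkit          3D

  7  6  0  0  0  0  0  0  0  0999 V2000
    0.9696    0.0874   -0.0206 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.1892    0.5088   -1.2274 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.1953    0.0730    0.0205 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.3690   -0.2177    0.8529 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8705    0.7906   -2.0341 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4389    1.3638   -0.9668 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4389   -0.3225   -1.5557 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  2  0  0  0  0
  1  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
M  END
$$$$
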