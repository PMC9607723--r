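fluoro
  growkit          3D

  2  1  0  0  0  0  0  0  0  0999 V2000
    0.8472   -0.0106    0.0303 F   0  0  0  0  0  0  0  0  0  0  0  0
    1.7864   -0.0106    0.0303 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
M  END
$$$$
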