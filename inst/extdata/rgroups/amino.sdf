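amino
  growkit          3D

  4  3  0  0  0  0  0  0  0  0999 V2000
    1.0367   -0.1046   -0.0461 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.0541   -0.0476   -0.0587 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7251    0.2353   -0.9548 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7251    0.5870    0.6344 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
M  END
$$$$
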