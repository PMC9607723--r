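trifluoromethyl
  growkit          3D

  5  4  0  0  0  0  0  0  0  0999 V2000
    0.9377    0.0269   -0.0957 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5046   -1.0855    0.5345 F   0  0  0  0  0  0  0  0  0  0  0  0
    0.5046    1.0965    0.6048 F   0  0  0  0  0  0  0  0  0  0  0  0
    2.2871    0.0258   -0.0603 F   0  0  0  0  0  0  0  0  0  0  0  0
    0.5733    0.0601   -1.1257 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
M  END
$$$$
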