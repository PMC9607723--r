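ethoxy
  growkit          3D

  9  8  0  0  0  0  0  0  0  0999 V2000
    1.0559   -0.0839   -0.0304 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.4755   -0.0708   -0.0356 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9833   -1.3974    0.4878 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7614    0.7783   -0.3706 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8226    0.7503    0.5987 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8226    0.0960   -1.0596 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6175   -1.5769    1.5042 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.0766   -1.4206    0.4970 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.6175   -2.2225   -0.1322 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  4  1  0  0  0  0
  2  3  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
  3  7  1  0  0  0  0
  3  8  1  0  0  0  0
  3  9  1  0  0  0  0
M  END
$$$$
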