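tert-butyl
  growkit          3D

 14 13  0  0  0  0  0  0  0  0999 V2000
    1.0881    0.0304    0.0584 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5672   -1.3916    0.2537 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.5672    0.9451    1.1646 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.6149    0.0397    0.0346 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7223    0.4062   -0.9057 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9082   -1.8102    1.2070 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9177   -2.0490   -0.5488 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5277   -1.4100    0.2489 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9082    0.6080    2.1497 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5277    0.9619    1.1735 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.9177    1.9722    1.0188 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.0274   -0.3289    0.9803 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9963    1.0532   -0.1282 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9963   -0.5962   -0.7712 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  2  8  1  0  0  0  0
  3  9  1  0  0  0  0
  3 10  1  0  0  0  0
  3 11  1  0  0  0  0
  4 12  1  0  0  0  0
  4 13  1  0  0  0  0
  4 14  1  0  0  0  0
M  END
$$$$
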