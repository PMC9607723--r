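isopropyl
  growkit          3D

 11 10  0  0  0  0  0  0  0  0999 V2000
    0.3608    0.3135    0.0313 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2767   -0.3037    1.0744 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.7488   -0.1106    0.7361 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.8545    0.4199   -0.9366 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.5232   -0.3159   -0.1076 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0226    1.2985    0.3579 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0771   -1.3765    1.1583 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0681    0.1366    2.0592 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9999    0.9502    0.6505 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.9953   -0.6015   -0.2126 H   0  0  0  0  0  0  0  0  0  0  0  0
    3.3816   -0.5522    1.5143 H   0  0  0  0  0  0  0  0  0  0  0  0
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
M  END
$$$$
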