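benzyl
  growkit          3D

 15 15  0  0  0  0  0  0  0  0999 V2000
    2.4901   -0.0085   -0.0123 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9903    0.0027   -0.0011 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2799    1.2088    0.0013 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1160    1.2069    0.0030 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.8131   -0.0000    0.0022 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1146   -1.2060    0.0020 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.2812   -1.2055    0.0006 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.8991    1.0072    0.0036 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8560   -0.5035   -0.9176 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8713   -0.5370    0.8673 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8085    2.1593    0.0007 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6594    2.1480    0.0037 H   0  0  0  0  0  0  0  0  0  0  0  0
   -2.8997   -0.0004    0.0012 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6571   -2.1478    0.0017 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8143   -2.1534   -0.0007 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  8  1  0  0  0  0
  1  9  1  0  0  0  0
  1 10  1  0  0  0  0
  2  3  1  0  0  0  0
  2  7  2  0  0  0  0
  3  4  2  0  0  0  0
  3 11  1  0  0  0  0
  4  5  1  0  0  0  0
  4 12  1  0  0  0  0
  5  6  2  0  0  0  0
  5 13  1  0  0  0  0
  6  7  1  0  0  0  0
  6 14  1  0  0  0  0
  7 15  1  0  0  0  0
M  END
$$$$
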