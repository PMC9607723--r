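uracil-1-yl
  growkit          3D

 12 12  0  0  0  0  0  0  0  0999 V2000
   -1.1743   -1.0385    0.0132 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0299   -1.7856   -0.0017 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.1698   -1.2004   -0.0158 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2396    0.2751   -0.0093 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3193    0.8541   -0.0116 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.0412    0.9314    0.0002 N   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1862    0.3306    0.0104 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.2320    0.9706    0.0164 O   0  0  0  0  0  0  0  0  0  0  0  0
   -2.0840   -1.4860    0.0241 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1495   -2.8643   -0.0024 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.1022   -1.7479   -0.0305 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.0611    1.9386    0.0028 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  7  1  0  0  0  0
  1  9  1  0  0  0  0
  2  3  2  0  0  0  0
  2 10  1  0  0  0  0
  3  4  1  0  0  0  0
  3 11  1  0  0  0  0
  4  5  2  0  0  0  0
  4  6  1  0  0  0  0
  6  7  1  0  0  0  0
  6 12  1  0  0  0  0
  7  8  2  0  0  0  0
M  END
$$$$
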