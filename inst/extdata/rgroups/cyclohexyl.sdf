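cyclohexyl
  growkit          3D

 18 18  0  0  0  0  0  0  0  0999 V2000
   -1.4206    0.3280   -0.2206 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.9908   -1.0650    0.2341 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4252   -1.3905   -0.2336 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.4200   -0.3281    0.2262 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.9945    1.0659   -0.2274 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4255    1.3934    0.2308 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.4146    0.5571    0.1805 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.5045    0.3455   -1.3141 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.6907   -1.8136   -0.1534 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.0352   -1.1204    1.3288 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.4422   -1.4575   -1.3282 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.7260   -2.3708    0.1522 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.4166   -0.5579   -0.1681 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.4959   -0.3483    1.3205 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.0471    1.1250   -1.3218 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.6917    1.8127    0.1678 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7249    2.3706   -0.1629 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4449    1.4685    1.3250 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  1  0  0  0  0
  1  7  1  0  0  0  0
  1  8  1  0  0  0  0
  2  3  1  0  0  0  0
  2  9  1  0  0  0  0
  2 10  1  0  0  0  0
  3  4  1  0  0  0  0
  3 11  1  0  0  0  0
  3 12  1  0  0  0  0
  4  5  1  0  0  0  0
  4 13  1  0  0  0  0
  4 14  1  0  0  0  0
  5  6  1  0  0  0  0
  5 15  1  0  0  0  0
  5 16  1  0  0  0  0
  6 17  1  0  0  0  0
  6 18  1  0  0  0  0
M  END
$$$$
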