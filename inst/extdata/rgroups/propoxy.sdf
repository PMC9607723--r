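propoxy
  growkit          3D

 12 11  0  0  0  0  0  0  0  0999 V2000
    0.9622    0.0833   -0.0062 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.3824    0.1099   -0.0288 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.9115   -1.0113    0.8522 C   0  0  0  0  0  0  0  0  0  0  0  0
    4.4295   -1.0400    0.8742 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6548    0.8092   -0.5755 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7185    1.0851    0.3376 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.7167   -0.0162   -1.0634 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5260   -1.9741    0.4949 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.5260   -0.8927    1.8719 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8328   -1.1959   -0.1314 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.7853   -1.8540    1.5135 H   0  0  0  0  0  0  0  0  0  0  0  0
    4.8329   -0.1000    1.2642 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  5  1  0  0  0  0
  2  3  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  3  4  1  0  0  0  0
  3  8  1  0  0  0  0
  3  9  1  0  0  0  0
  4 10  1  0  0  0  0
  4 11  1  0  0  0  0
  4 12  1  0  0  0  0
M  END
$$$$
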