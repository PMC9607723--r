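methylamino
  growkit          3D

  7  6  0  0  0  0  0  0  0  0999 V2000
    1.0211    0.0852    0.0525 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.4730    0.0893    0.0389 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6773   -0.5467   -0.6694 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.6773    1.0121   -0.1951 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8556   -0.9083    0.2716 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8556    0.7882    0.7879 H   0  0  0  0  0  0  0  0  0  0  0  0
    2.8480    0.3884   -0.9440 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
M  END
$$$$
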