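methylsulfonyl
  growkit          3D

  8  7  0  0  0  0  0  0  0  0999 V2000
    1.1046   -0.0509   -0.0691 S   0  0  0  0  0  0  0  0  0  0  0  0
    0.4894    1.5610   -0.4679 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.4799   -1.0064   -0.9613 O   0  0  0  0  0  0  0  0  0  0  0  0
    2.5449    0.0349    0.0627 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.6396   -0.3379    1.1602 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8476    1.8295   -1.4635 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8644    2.2693    0.2729 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6014    1.5302   -0.4538 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  2  0  0  0  0
  1  4  2  0  0  0  0
  1  5  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  2  8  1  0  0  0  0
M  END
$$$$
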