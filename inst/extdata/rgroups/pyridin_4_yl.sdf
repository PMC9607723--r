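pyridin-4-yl
  growkit          3D

 11 11  0  0  0  0  0  0  0  0999 V2000
    1.4330    0.0516    0.0010 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6880    1.2260    0.0015 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6942    1.1256    0.0022 C   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3624   -0.0485    0.0055 N   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6120   -1.1719    0.0069 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7738   -1.1733    0.0033 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.5185    0.0904   -0.0011 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.1715    2.1963    0.0013 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.3198    2.0134    0.0001 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.1726   -2.1023    0.0114 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.3254   -2.1063    0.0027 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  6  2  0  0  0  0
  1  7  1  0  0  0  0
  2  3  2  0  0  0  0
  2  8  1  0  0  0  0
  3  4  1  0  0  0  0
  3  9  1  0  0  0  0
  4  5  2  0  0  0  0
  5  6  1  0  0  0  0
  5 10  1  0  0  0  0
  6 11  1  0  0  0  0
M  END
$$$$
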