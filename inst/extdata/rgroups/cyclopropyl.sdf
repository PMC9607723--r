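cyclopropyl
  growkit          3D

  9  9  0  0  0  0  0  0  0  0999 V2000
   -0.0282    0.8659   -0.0584 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.7642   -0.4036    0.0727 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.7373   -0.4520    0.0727 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0441    1.3581   -1.0238 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.0500    1.5420    0.7886 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2780   -0.5897    1.0086 H   0  0  0  0  0  0  0  0  0  0  0  0
    1.2865   -0.7689   -0.8042 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2380   -0.6707    1.0086 H   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2349   -0.8502   -0.8042 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  1  0  0  0  0
  1  4  1  0  0  0  0
  1  5  1  0  0  0  0
  2  3  1  0  0  0  0
  2  6  1  0  0  0  0
  2  7  1  0  0  0  0
  3  8  1  0  0  0  0
  3  9  1  0  0  0  0
M  END
$$$$
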