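carbamoyl
  growkit          3D

  6  5  0  0  0  0  0  0  0  0999 V2000
    1.0728   -0.0488   -0.1265 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.3382   -1.0127   -0.7404 N   0  0  0  0  0  0  0  0  0  0  0  0
    2.2937   -0.0402   -0.1210 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.4547    0.7205    0.3635 H   0  0  0  0  0  0  0  0  0  0  0  0
    0.8322   -1.7573   -1.2146 H   0  0  0  0  0  0  0  0  0  0  0  0
   -0.6716   -1.0127   -0.7404 H   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0  0  0  0
  1  3  2  0  0  0  0
  1  4  1  0  0  0  0
  2  5  1  0  0  0  0
  2  6  1  0  0  0  0
M  END
$$$$
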