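aspirin
     RDKit          2D

 13 13  0  0  0  0  0  0  0  0999 V2000
   -3.8123   -1.2868    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -2.6987   -0.2818    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -3.0122    1.1850    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -1.2716   -0.7438    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
   -0.1580    0.2612    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
   -0.4715    1.7281    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    0.6420    2.7330    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.0691    2.2711    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    2.3827    0.8043    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.2691   -0.2007    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    1.5826   -1.6676    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0
    3.0097   -2.1295    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
    0.4690   -2.6725    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0
  1  2  1  0
  2  3  2  0
  2  4  1  0
  4  5  1  0
  5  6  2  0
  6  7  1  0
  7  8  2  0
  8  9  1  0
  9 10  2  0
 10 11  1  0
 11 12  2  0
 11 13  1  0
 10  5  1  0
M  END
$$$$
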