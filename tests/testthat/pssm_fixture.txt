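Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts

             A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V   A   R   N   D   C   Q   E   G   H   I   L   K   M   F   P   S   T   W   Y   V
    1 M   -2  -3  -4  -4  -2  -1  -3  -4  -3   1   2  -2   7  -1  -4  -2  -1  -3  -2   0    0   0   0   0   0   0   0   0   0   0   0   0  96   0   0   0   0   4   0   0  1.98 0.03
    2 K    0   0   5  -1  -2   5   0   4   1  -4  -2   7   2   5   2   6  -5   5  -2   3    0   0   4   0   0   0   0   0   0   0   0  96   0   0   0   0   0   0   0   0  1.94 0.03
    3 T   -1   2   3  -1   0   2   7   3  -4   6  -1   2   4   2   4   4   7   5  -4   1    0   0   0   0   4   0   0   0   0   0   0   0   0   0   0   0  96   0   0   0  1.04 0.03
    4 A    7  -3  -1   3   1   2   6  -4  -4   2   7   0   4   7   2   1   3   3   2   0   96   0   0   0   0   0   0   0   0   0   0   4   0   0   0   0   0   0   0   0  0.88 0.03
    5 Y   -2  -5   5   7   6   1   6   1  -4  -5  -5  -5   6   5  -4   3   4  -5   7   3    0   0   0   0   0   0   0   0   4   0   0   0   0   0   0   0   0   0  96   0  1.62 0.03
    6 L   -2   5   2  -2   7   6   0   2   2   3   7  -3  -4   7  -4  -1   5   1  -4  -2    0   4   0   0   0   0   0   0   0   0  96   0   0   0   0   0   0   0   0   0  1.61 0.03
    7 W    2  -1  -5  -1   3   6   0   5   2   5   7   4   6   7  -4  -2  -5   7   7  -2    0   0   0   0   0   0   0   0   0   4   0   0   0   0   0   0   0  96   0   0  1.54 0.03
    8 G    6   7   1   6   4  -3  -2   7  -5   5   0   4   6   4   7   4   5   3   2  -5    0   0   0   0   0   0   0  96   0   0   4   0   0   0   0   0   0   0   0   0  1.36 0.03
    9 E   -4   6  -3   2  -1  -4   7   6  -4  -5   5   1  -4  -1  -5   0   6   2  -4   1    0   0   0   0   0   0  96   0   0   0   0   0   0   0   4   0   0   0   0   0  0.39 0.03
   10 V    6   0   7  -2   3  -3  -4   2  -1  -3  -4   3   3   6   2   7  -1  -4   0   7    0   0   0   0   0   0   0   0   0   0   0   0   0   0   4   0   0   0   0  96  0.80 0.03

                      K         Lambda
Standard Ungapped    0.1       0.3
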