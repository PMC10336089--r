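HEADER    SYNTHETIC CALPHA TRACE
ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00  0.00           C
ATOM      2  CA  GLY A   2      12.902   7.441  -3.514  1.00  0.00           C
ATOM      3  CA  SER A   3      15.342   5.232  -1.740  1.00  0.00           C
ATOM      4  CA  LEU A   4      17.890   6.800   0.540  1.00  0.00           C
END
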