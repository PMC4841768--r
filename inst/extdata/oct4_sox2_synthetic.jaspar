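>OCT4-SOX2_synthetic composite HMG+octamer motif (synthetic counts, not a database matrix)
A  [  6 82  6  6  6  6  6 82  6  6  6 82 82 82  6 ]
C  [ 82  6  6  6  6  6  6  6  6  6 82  6  6  6  6 ]
G  [  6  6  6  6 82  6  6  6  6 82  6  6  6  6  6 ]
T  [  6  6 82 82  6 82 82  6 82  6  6  6  6  6 82 ]
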