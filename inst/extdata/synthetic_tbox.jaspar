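>synthetic_tbox	synthetic T-box-like test matrix
A  [  2 94  2  2  2  2  2  2 94 94 ]
C  [ 94  2  2  2  2  2  2  2  2  2 ]
G  [  2  2 94 94  2 94  2 94  2  2 ]
T  [  2  2  2  2 94  2 94  2  2  2 ]
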