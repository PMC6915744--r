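>SYN0001.1 SYNTF1
A  [ 85   5   5   5  85   5   5   5   5  85   5   5 ]
C  [  5   5  85  85   5   5   5  85   5   5   5  85 ]
G  [  5  85   5   5   5  85   5   5   5   5  85   5 ]
T  [  5   5   5   5   5   5  85   5  85   5   5   5 ]
>SYN0002.1 SYNTF2
A  [  5   5  85   5   5   5  85  85   5   5 ]
C  [ 85   5   5  85   5   5   5   5   5  85 ]
G  [  5  85   5   5  85   5   5   5  85   5 ]
T  [  5   5   5   5   5  85   5   5   5   5 ]
>SYN0003.1 SYNTF3
A  [  5   5   5  85   5   5   5   5  85   5   5   5 ]
C  [  5  85   5   5   5  85   5   5   5   5  85   5 ]
G  [ 85   5   5   5  85   5   5  85   5   5   5  85 ]
T  [  5   5  85   5   5   5  85   5   5  85   5   5 ]
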