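>GBS_synthetic glucocorticoid-receptor-like inverted repeat (synthetic counts)
A [ 28  8 30 88  2 90  30 28 30  2  2  2 30  4 28 ]
C [ 22  2 20  4 92  2  22 22 20  2  2  4 20 88 22 ]
G [ 26 86 26  4  2  4  24 26 24  4 92  2 26  4 26 ]
T [ 24  4 24  4  4  4  24 24 26 92  4 92 24  4 24 ]
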