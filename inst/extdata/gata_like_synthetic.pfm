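>SYNGATA1 GATA_like_synthetic
A [ 12  2 16  1 16 10 ]
C [  2  2  2  1  1  3 ]
G [  2 14  1  1  2  3 ]
T [  4  2  1 17  1  4 ]
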