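MEME version 4

ALPHABET= ACGT

strands: + -

Background letter frequencies
A 0.30000 C 0.20000 G 0.20000 T 0.30000

MOTIF HNS_A_synthetic
letter-probability matrix: alength= 4 w= 9 nsites= 40 E= 1e-05
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.050000 0.850000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.850000 0.050000 0.050000 0.050000
 0.050000 0.050000 0.850000 0.050000
 0.050000 0.050000 0.050000 0.850000
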