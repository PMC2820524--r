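>dmrt_like_synthetic (synthetic count matrix whose consensus is CTGCAACAATGCATT)
A [  1  1  1  1 12 12  1 12 12  1  1  1 12  1  1 ]
C [ 12  1  1 12  1  1 12  1  1  1  1 12  1  1  1 ]
G [  1  1 12  1  1  1  1  1  1  1 12  1  1  1  1 ]
T [  1 12  1  1  1  1  1  1  1 12  1  1  1 12 12 ]
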