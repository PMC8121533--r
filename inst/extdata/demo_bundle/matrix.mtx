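%%MatrixMarket matrix coordinate integer general
%
4 3 6
1 1 5
2 1 1
3 2 2
4 2 7
1 3 3
4 3 1
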