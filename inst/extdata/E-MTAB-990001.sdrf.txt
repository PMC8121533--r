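Source Name	Characteristics[organism]	Comment[library construction]	Derived Array Data File	Comment[submitted file name]
D1	Homo sapiens	10x Genomics 3 prime v2	raw_data_10x.txt	raw_data_10x.txt
D2	Homo sapiens	10x Genomics 3 prime v2	meta_10x.txt	meta_10x.txt
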