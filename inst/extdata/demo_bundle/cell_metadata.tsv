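cell	cell_type	cluster	UMAP_1	UMAP_2
AAACCTGA-1	b_cell	0	-3.2	1.1
AAACGGGT-1	melanoma	1	4.5	-0.2
AAAGATGC-1	myeloid	2	0.8	2.9
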