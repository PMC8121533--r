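ENSG000001	GENE1
ENSG000002	GENE2
ENSG000003	GENE3
ENSG000004	GENE4
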