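field	value
n_inspected	173
n_true_single_cell	156
n_called_positive	27
n_true_positive	24
n_missed_with_metadata	10
n_with_cell_type	22
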