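gene	qvalue
k_in	0.049
k_edge	0.05
k_out	0.2
k_strong	0.001
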