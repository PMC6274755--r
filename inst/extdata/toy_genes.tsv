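feature_id	S1	S2	S3	S4	S5	S6
g_low	0.2	0.9	0.5	0.1	0	0.8
g_edge	0	0	0	0	0	1.0
g_hi	5	6	2	8	3	4
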