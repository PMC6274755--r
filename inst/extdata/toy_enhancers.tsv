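enhancer_id	S1	S2	S3	S4	S5	S6
e_two	3	0	0	2	0	0
e_three	1	2	0	0	3	0
e_all	1	1	2	3	1	2
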