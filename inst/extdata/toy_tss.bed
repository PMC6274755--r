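chr1	100000	100001	tf_prom
chr1	1100	1101	t_inside
chr1	1500	1501	t_near
chr1	2200	2201	t_edge
chr1	2300	2301	t_far
chr2	1500	1501	t_otherchrom
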