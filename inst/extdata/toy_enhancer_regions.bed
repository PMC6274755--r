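chr1	149499	150499	enh_near
chr1	149501	150501	enh_far
chr2	99500	100500	enh_chr2
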