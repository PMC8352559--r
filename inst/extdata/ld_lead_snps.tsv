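snp_a	snp_b	r2
rs6127099	rs35194449	0.38
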