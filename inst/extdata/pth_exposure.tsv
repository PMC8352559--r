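SNP	effect_allele	other_allele	eaf	beta	se	pval	n
rs6127099	T	A	0.34	0.07	0.003	2.4e-72	29155
rs4074995	G	A	0.71	0.03	0.003	3.3e-23	29155
rs219779	G	A	0.75	0.04	0.003	8.9e-22	29155
rs4443100	G	C	0.32	0.02	0.003	4.1e-11	29155
rs73186030	T	C	0.14	0.03	0.003	1.2e-9	29155
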