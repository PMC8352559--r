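SNP	effect_allele	other_allele	eaf	beta	se	pval	n
rs6127099	T	A	0.34	-0.0162	0.0086	0.06143	455221
rs4074995	G	A	0.71	-0.016	0.0086	0.06259	455221
rs219779	G	A	0.75	-0.0157	0.0086	0.0679	455221
rs4443100	G	C	0.32	-0.0224	0.0083	0.006762	455221
rs73186030	T	C	0.14	-0.0382	0.0114	0.000774	455221
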