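exposure: pth_lead6_synthetic.tsv
outcome: oa_outcome.tsv
ld: ld_lead_snps.tsv
p_threshold: 5.0e-8
r2_threshold: 0.01
intermediate_eaf: 0.42
ivw_mode: multiplicative_random
n_boot: 1000
presso_n_sim: 10000
seed: 20210726
exclude_snps:
  - rs4074995
power:
  n_total: 455221
  n_cases: 77052
  r2_total: 0.045
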