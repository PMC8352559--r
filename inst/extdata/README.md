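# Packaged example data

Summary statistics for the five independent genome-wide-significant serum
parathyroid hormone (PTH) instruments and their effects on osteoarthritis
(OA), as published:

- `pth_exposure.tsv` — exposure associations (N = 29,155).
- `oa_outcome.tsv` — outcome associations on the same effect alleles
  (N = 455,221; log-odds scale). Outcome allele frequencies are not
  published per SNP and mirror the exposure values.
- `pth_lead6_synthetic.tsv` — the exposure table extended with the sixth
  lead SNP rs35194449 (p = 1.8e-10), which LD pruning removes. Only its
  p-value and its LD with rs6127099 are published; its beta/se/eaf columns
  are **synthetic placeholders** (pruning never reads them).
- `ld_lead_snps.tsv` — the single published LD pair
  (rs6127099, rs35194449, r² = 0.38).
- `pth_oa_config.yaml` — pipeline configuration reproducing the full
  analysis from these files.
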