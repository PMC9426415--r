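# Case/control cohort at the test-set shape: 40 metastatic cancers
# against 17 benign + 9 healthy-normal controls, plasma matrix.
n_cancer: 40
n_benign: 17
n_normal: 9
matrix: plasma
cancer:
  active_gene_prob: 0.17
  copies_meanlog: 5.703782
  copies_sdlog: 1.2
  background_rate: 0.02
control:
  active_gene_prob: 0.0
  copies_meanlog: 5.703782
  copies_sdlog: 1.2
  background_rate: 0.02
actb_ct_range_cancer:
- 16.0
- 27.8
actb_ct_range_normal:
- 21.0
- 27.4
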