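# Spike-in replicate experiment: copies of fully methylated DNA per
# condition, replicates per condition, and the blood matrix.
copies:
- 0
- 75
- 150
- 300
replicates: 11
matrix: plasma
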