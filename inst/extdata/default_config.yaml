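panel:
  target_genes:
  - HOXB4
  - RASGRF2
  - AKR1B1
  - TM6SF1
  - COL6A2
  - HIST1H3C
  - TMEFF2
  - RASSF1
  - ZNF671
  reference_gene: ACTB
layout:
  cartridges:
    A:
    - AKR1B1
    - TM6SF1
    - ZNF671
    - TMEFF2
    B:
    - COL6A2
    - HIST1H3C
    - RASGRF2
    - HOXB4
    - RASSF1
constants:
  no_signal_ct: 45.0
  censor_offset: 13.0
  m_scale: 1200.0
  cm_threshold: 38.5
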