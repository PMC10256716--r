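# Illustrative phenotype code-to-class map (HPO and ICD-10-like codes).
# Real analyses replace this with their own clinical query set.
renal:
  - "HP:0000090"   # nephronophthisis
  - "HP:0003774"   # stage 5 chronic kidney disease
  - "N18.4"        # chronic kidney disease, stage 4
  - "N18.5"        # chronic kidney disease, stage 5
retinal:
  - "HP:0000556"   # retinal dystrophy
  - "H35.5"        # hereditary retinal dystrophy
neurological:
  - "HP:0001263"   # global developmental delay
  - "G93.89"       # other specified disorders of brain
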