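CC(=O)Oc1ccccc1C(=O)O aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
CC(=O)Nc1ccc(O)cc1 paracetamol
CN(C)C(=N)N=C(N)N metformin
COc1ccc2cc(ccc2c1)C(C)C(=O)O naproxen
CCCCNC(=O)NS(=O)(=O)c1ccc(C)cc1 tolbutamide
Cc1cnc(cn1)C(=O)NCCc1ccc(cc1)S(=O)(=O)NC(=O)NC1CCCCC1 glipizide
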