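CC1C(C(C(O1)OC2C(C(C(C(C2O)O)NC(=N)N)O)NC(=N)N)OC3C(C(C(C(O3)CO)O)O)NC)(C=O)O Streptomycin
CC(=O)Oc1ccccc1C(=O)O Aspirin
CC(C)Cc1ccc(cc1)C(C)C(=O)O Ibuprofen
CC(=O)Nc1ccc(O)cc1 Paracetamol
Cn1cnc2c1c(=O)n(C)c(=O)n2C Caffeine
COc1ccc2cc(ccc2c1)C(C)C(=O)O Naproxen
Clc1ccccc1C1=NCC(=O)Nc2ccc(cc12)N(=O)=O Clonazepam-like
CCO Ethanol
CC(=O)[O-] Acetate
c1ccccc1 Benzene
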