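CC(=O)Oc1ccccc1C(=O)O aspirin
CN1C=NC2=C1C(=O)N(C)C(=O)N2C caffeine
COc1cc(/C=C/C(=O)CC(=O)/C=C/c2ccc(O)c(OC)c2)ccc1O curcumin
C1=CC(=CC=C1CCN)O tyramine
CC(C)Cc1ccc(cc1)C(C)C(=O)O ibuprofen
Clc1ccccc1-c1nc2ccccc2[nH]1 clobenzimidazole
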