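compound_id,name,smiles
MOL001,afatinib,CN(C)C/C=C/C(=O)Nc1cc2c(Nc3ccc(F)c(Cl)c3)ncnc2cc1OC1CCOC1
MOL002,dacomitinib,COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1NC(=O)/C=C/CN1CCCCC1
MOL003,neratinib,CCOc1cc2ncc(C#N)c(Nc3ccc(OCc4ccccn4)c(Cl)c3)c2cc1NC(=O)/C=C/CN(C)C
MOL004,acrylamide,C=CC(=O)N
MOL005,aspirin,CC(=O)Oc1ccccc1C(=O)O
MOL006,caffeine,Cn1cnc2c1c(=O)n(C)c(=O)n2C
MOL007,ibuprofen,CC(C)Cc1ccc(C(C)C(=O)O)cc1
MOL008,paracetamol,CC(=O)Nc1ccc(O)cc1
MOL009,ethanol,CCO
MOL010,nicotine,CN1CCCC1c1cccnc1
MOL011,naphthalene,c1ccc2ccccc2c1
MOL012,cholesterol,CC(C)CCCC(C)C1CCC2C1(C)CCC1C2CC=C2CC(O)CCC12C
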