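drug_name	smiles	is_steroid
TESTOSTERONE	CC12CCC3C(C1CCC2O)CCC4=CC(=O)CCC34C	TRUE
ESTRADIOL	CC12CCC3C(C1CCC2O)CCC4=C3C=CC(=C4)O	TRUE
HYDROCORTISONE	CC12CCC(=O)C=C1CCC3C2C(O)CC4(C)C3CCC4(O)C(=O)CO	TRUE
PROGESTERONE	CC(=O)C1CCC2C1(C)CCC3C2CCC4=CC(=O)CCC34C	TRUE
PREDNISOLONE	CC12CC(O)C3C(CCC4=CC(=O)C=CC34C)C1CCC2(O)C(=O)CO	TRUE
CHOLESTEROL	CC(C)CCCC(C)C1CCC2C1(C)CCC3C2CC=C4CC(O)CCC34C	TRUE
SPIRONOLACTONE	CC(=O)SC1CC2=CC(=O)CCC2(C)C2CCC3(C)C(CCC34CCC(=O)O4)C12	TRUE
NORETHISTERONE	CC12CCC3C(CCC4=CC(=O)CCC34)C1CCC2(O)C#C	TRUE
DEXAMETHASONE	CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO	TRUE
ESTRONE	CC12CCC3C(C1CCC2=O)CCC4=C3C=CC(=C4)O	TRUE
ETHANOL	CCO	FALSE
ASPIRIN	CC(=O)OC1=CC=CC=C1C(=O)O	FALSE
CAFFEINE	CN1C=NC2=C1C(=O)N(C)C(=O)N2C	FALSE
IBUPROFEN	CC(C)CC1=CC=C(C=C1)C(C)C(=O)O	FALSE
PHENANTHRENE	C1=CC2=CC=C3C=CC=CC3=C2C=C1	FALSE
DIETHYLSTILBESTROL	CCC(=C(CC)C1=CC=C(O)C=C1)C2=CC=C(O)C=C2	FALSE
MORPHINE	CN1CCC23C4C1CC5=C2C(=C(C=C5)O)OC3C(C=C4)O	FALSE
WARFARIN	CC(=O)CC(C1=CC=CC=C1)C2=C(O)C3=CC=CC=C3OC2=O	FALSE
GLUCOSE	OCC1OC(O)C(O)C(O)C1O	FALSE
TAMOXIFEN	CCC(=C(C1=CC=CC=C1)C2=CC=C(OCCN(C)C)C=C2)C3=CC=CC=C3	FALSE
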