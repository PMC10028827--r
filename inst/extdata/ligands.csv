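ligand_id,smiles,substituent_class,tau_cal_s,tau_exp_s,kd_nM,ki_nlx_nM
FEN,CCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1,parent,,,,
BUF,CCCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
FBUF,CCCC(=O)N(c1ccc(F)cc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
FIBUF,CC(C)C(=O)N(c1ccc(F)cc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
IBUF,CC(C)C(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
VAF,CCCCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
FUR,O=C(c1ccco1)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1,R2_modified,,,,
MNFEN,CCC(=O)N(c1ccccc1)C1CCN(C)CC1,R1_R4_modified,,,,
MNCAR,CCC(=O)N(c1ccccc1)C1(C(=O)OC)CCN(C)CC1,R1_R4_modified,,,,
CAR,CCC(=O)N(c1ccccc1)C1(C(=O)OC)CCN(CCc2ccccc2)CC1,R1_R4_modified,,,,
LOF,CCC(=O)N(c1ccccc1)C1(C(=O)OC)C(C)CN(CCc2ccccc2)CC1,R1_R4_modified,,,,
METM,CCC(=O)N(c1ccccc1)C1(COC)CCN(CCc2ccccc2)CC1,R1_R4_modified,,,,
SUF,CCC(=O)N(c1ccccc1)C1(COC)CCN(CCc2cccs2)CC1,R1_R4_modified,,,,
ALF,CCN1N=NN(CCN2CCC(COC)(N(C(=O)CC)c3ccccc3)CC2)C1=O,R1_R4_modified,,,,
REMI,CCC(=O)N(c1ccccc1)C1(C(=O)OC)CCN(CCC(=O)OC)CC1,R1_R4_modified,,,,
MOP,CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5,morphinan,,,,
BUP,CC(C)(C)C(C)(O)C1CC23CCC1(OC)C1Oc4c(O)ccc5c4C2(CCN3CC2CC2)C1C5,morphinan,,,,
NLX,C=CCN1CCC23c4c5ccc(O)c4OC2C(=O)CCC3(O)C1C5,morphinan,,,,
NTX,C1CC1CN1CCC23c4c5ccc(O)c4OC2C(=O)CCC3(O)C1C5,morphinan,,,,
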