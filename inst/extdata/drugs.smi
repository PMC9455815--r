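CC(=O)Oc1ccccc1C(=O)O	aspirin
Cn1cnc2c1c(=O)n(C)c(=O)n2C	caffeine
CC(C)Cc1ccc(cc1)C(C)C(=O)O	ibuprofen
CC(=O)Nc1ccc(O)cc1	paracetamol
COc1ccc2cc(ccc2c1)C(C)C(=O)O	naproxen
OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl	diclofenac
CC(C)NCC(O)COc1cccc2ccccc12	propranolol
CC(C)NCC(O)COc1ccc(CC(N)=O)cc1	atenolol
COCCc1ccc(OCC(O)CNC(C)C)cc1	metoprolol
CC(C)(C)NCC(O)c1ccc(O)c(CO)c1	salbutamol
CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1	diazepam
OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1	haloperidol
CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1	fluoxetine
CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12	sertraline
CN(C)CCCN1c2ccccc2CCc2ccccc21	imipramine
CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O	warfarin
CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21	chlorpromazine
CN(C)CCC=C1c2ccccc2CCc2ccccc21	amitriptyline
CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1	tamoxifen
Cc1cc(no1)NS(=O)(=O)c1ccc(N)cc1	sulfamethoxazole
COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC	trimethoprim
CN1CCCC1c1cccnc1	nicotine
CCC(CO)NCCNC(CC)CO	ethambutol
CCN(CC)CCOC(=O)c1ccc(N)cc1	procaine
CCN(CC)CC(=O)Nc1c(C)cccc1C	lidocaine
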