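smiles
CCc1ccccc1N
C1CCOC1CCl
CCC(=O)N
c1ccsc1S
CCSC
CC1CCCCC1C(=O)O
CCOCCBr
CC(C)(C)N
C1CCOC1Br
Cc1ccccc1CN
CC(C)CO
CCCCCCS
CC(=O)Oc1ccccc1C(=O)O
CC1CCCCC1Cl
CC1CCCCC1C(=O)N
C1CCNC1F
CCO
c1cc[nH]c1CO
OCC1CCCCC1
c1cc[nH]c1N(C)C
C1CCOC1F
CC(C)C
CCCCCNC
CC(N)C(=O)O
CC1CCCCC1C(=O)C
CC(C)CCCCl
C1CCCC1CO
SCC1CCCCC1
CC(C)CCC(=O)N
CCCCCCN
CSCC(N)C(=O)O
CCCCC(=O)O
CC1CCCCC1CO
c1ccsc1CCl
CNC(=O)C
Clc1ccccc1Cl
CCOCCOC
CCCCC
c1cc[nH]c1NC
CCOCNC
c1cc[nH]c1SC
C1CCCC1F
c1ccncc1C(=O)C
c1ccncc1Br
CCCC
C1CCCCC1C(=O)C
C1CCNC1C#N
CC(C)CC(=O)O
CCCN
Nc1ccccc1N
C1CCOC1O
CCOCCF
CSC(=O)C
c1ccsc1CS
CC(C)CC(=O)N
C1CCCC1S
C1CCCC1C(=O)C
c1ccncc1O
CC1CCCCC1NC
c1ccncc1
C1CCCCC1NC
CCCC(=O)C
CCCCCBr
c1ccccc1CS
CC(C)CCCl
CN1CCCC1
c1ccsc1CO
c1ccncc1C(=O)O
C1CCCC1N
CC(C)CF
NC(=O)CN
C1CCNC1Cl
CCCCCN(C)C
Cc1ccccc1C#N
c1ccncc1N
c1ccccc1CO
C1CCCC1OC
C1CCCC1SC
CCCCS
CCCCCCO
CC1CCCCC1F
C1CCCCC1Br
c1ccsc1F
C1CCNC1S
C1CCNC1CO
CC
CCOCCC(=O)O
c1ccsc1OC
CCCCCN
Cc1ccccc1CO
C1CCCC1CN
CC(C)CC(=O)C
C1CCCCC1CCl
CC(C)CCO
CCCOC
CC1CCCCC1O
CCc1ccccc1SC
C1CCOC1
c1ccncc1F
Cc1ccccc1CS
NCC1CCCCC1
C1CCOC1CN
C1CCNC1SC
c1ccncc1NC
c1ccccc1N(C)C
CC(C)CCNC
C1CCCC1Cl
CC(C)CC
CC(C)CCC(=O)C
C1CCNC1O
c1ccsc1C#N
CCOCCC(=O)C
CC(S)C(=O)O
CCCCN
CCCCCOC
c1ccccc1S
C1CCCC1C(=O)O
CCCCF
C1CCNC1N(C)C
c1ccncc1Cl
C1CCCCC1F
CCCCCS
C1CCCC1C#N
CCc1ccccc1N(C)C
Cc1ccccc1C(=O)N
Cc1ccccc1Br
CC(C)COC
CCCN(C)C
CC1CCCCC1N(C)C
CCCCC(=O)N
C1CCCC1CCl
C1CCOC1C#N
c1ccccc1O
c1cc[nH]c1CN
c1cc[nH]c1O
c1ccncc1SC
c1cc[nH]c1F
C1CCCC1CS
c1ccccc1CCl
CCCCl
CCCCCC(=O)C
CCCCCC(=O)N
CCOC(=O)CC
CCCF
CCCSC
C1CCCC1NC
CCc1ccccc1C#N
Cc1ccccc1NC
CC1CCCCC1Br
C1CCCCC1O
CC(C)CN
c1ccccc1C#N
CC(C)CCl
c1ccncc1C#N
CCOCCO
CCc1ccccc1O
C1CCOC1NC
CCc1ccccc1CN
Oc1ccccc1O
c1cc[nH]c1S
CCNC
C1CCCCC1OC
C1CCCCC1C(=O)O
CC(C)CS
CC1CCCCC1
OCCO
Oc1ccc(Cl)cc1
CC(C)CCS
CCOC(=O)C
Cc1ccccc1CCl
CCCBr
CC(Cl)C(=O)O
CCCCNC
c1ccccc1C(=O)N
C1CCOC1SC
CCC
CCOCC(=O)N
NCCN
c1ccsc1NC
CCOCCCS
CC(C)CNC
C1CCCCC1
ClCCCl
CC1CCCCC1N
c1ccsc1C(=O)C
CCOCN(C)C
CN1CCOCC1
c1ccccc1N
c1cc[nH]c1N
CCc1ccccc1C(=O)O
Cc1ccccc1
NCCOCCN
CCC(=O)C
c1ccncc1CN
Cc1ccccc1OC
c1ccsc1Cl
C1CCCCC1CN
CCOCCCl
CC1CCCCC1SC
C1CCNC1OC
CCOCF
C1CCCC1C(=O)N
c1ccsc1C(=O)O
CCCC(=O)N
SCCS
c1ccsc1N
c1ccsc1C(=O)N
CCS
CCCCCCCl
C1CCNC1NC
c1ccccc1Cl
CCCCC(=O)C
CC(C)(C)O
CCCC#N
c1ccccc1C(=O)O
c1ccncc1OC
CC(C)CCC(=O)O
CC(C)CSC
c1cc[nH]c1
c1ccncc1C(=O)N
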