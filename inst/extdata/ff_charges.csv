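resname,atom,charge
BB,N,-0.45
BB,H,0.31
BB,CA,0.14
BB,C,0.51
BB,O,-0.51
BB,OXT,-0.51
ALA,CB,0.00
VAL,CB,0.00
VAL,CG1,0.00
VAL,CG2,0.00
LEU,CB,0.00
LEU,CG,0.00
LEU,CD1,0.00
LEU,CD2,0.00
ILE,CB,0.00
ILE,CG1,0.00
ILE,CG2,0.00
ILE,CD1,0.00
MET,CB,0.00
MET,CG,0.06
MET,SD,-0.12
MET,CE,0.06
PHE,CB,0.00
PHE,CG,0.00
PHE,CD1,0.00
PHE,CD2,0.00
PHE,CE1,0.00
PHE,CE2,0.00
PHE,CZ,0.00
TRP,CB,0.00
TRP,CG,0.00
TRP,CD1,0.06
TRP,CD2,0.00
TRP,NE1,-0.61
TRP,HE1,0.38
TRP,CE2,0.17
TRP,CE3,0.00
TRP,CZ2,0.00
TRP,CZ3,0.00
TRP,CH2,0.00
SER,CB,0.23
SER,OG,-0.66
SER,HG,0.43
THR,CB,0.23
THR,OG1,-0.66
THR,HG1,0.43
THR,CG2,0.00
CYS,CB,0.11
CYS,SG,-0.54
CYS,HG,0.43
CYX,CB,0.08
CYX,SG,-0.08
CYM,CB,-0.20
CYM,SG,-0.80
ASP,CB,-0.16
ASP,CG,0.62
ASP,OD1,-0.73
ASP,OD2,-0.73
GLU,CB,0.00
GLU,CG,-0.16
GLU,CD,0.62
GLU,OE1,-0.73
GLU,OE2,-0.73
LYS,CB,0.00
LYS,CG,0.00
LYS,CD,0.00
LYS,CE,0.21
LYS,NZ,-0.50
LYS,HZ1,0.43
LYS,HZ2,0.43
LYS,HZ3,0.43
ARG,CB,0.00
ARG,CG,0.00
ARG,CD,0.20
ARG,NE,-0.70
ARG,HE,0.44
ARG,CZ,0.82
ARG,NH1,-0.80
ARG,HH11,0.46
ARG,HH12,0.46
ARG,NH2,-0.80
ARG,HH21,0.46
ARG,HH22,0.46
HIS,CB,0.00
HIS,CG,0.22
HIS,ND1,-0.70
HIS,CD2,0.10
HIS,CE1,0.44
HIS,NE2,-0.55
HIS,HE2,0.49
ASN,CB,0.00
ASN,CG,0.55
ASN,OD1,-0.55
ASN,ND2,-0.62
ASN,HD21,0.31
ASN,HD22,0.31
GLN,CB,0.00
GLN,CG,0.00
GLN,CD,0.55
GLN,OE1,-0.55
GLN,NE2,-0.62
GLN,HE21,0.31
GLN,HE22,0.31
TYR,CB,0.00
TYR,CG,0.00
TYR,CD1,0.00
TYR,CD2,0.00
TYR,CE1,0.00
TYR,CE2,0.00
TYR,CZ,0.11
TYR,OH,-0.54
TYR,HH,0.43
PRO,N,-0.14
PRO,CB,0.00
PRO,CG,0.00
PRO,CD,0.00
PRD,C1,0.00
PRD,C2,0.00
PRD,C3,0.55
PRD,O1,-0.55
PRD,N1,-0.62
PRD,H11,0.31
PRD,H12,0.31
HOH,O,-0.834
HOH,H1,0.417
HOH,H2,0.417
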