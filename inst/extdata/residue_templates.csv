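restype,atom,p1,p2,p3,bond,angle,torsion
ALA,,,,,,,
GLY,,,,,,,
SER,OG,CB,CA,N,1.417,110.8,chi1
CYS,SG,CB,CA,N,1.808,114.4,chi1
THR,OG1,CB,CA,N,1.433,109.6,chi1
THR,CG2,CB,CA,N,1.521,110.5,chi1-120
VAL,CG1,CB,CA,N,1.527,110.5,chi1
VAL,CG2,CB,CA,N,1.527,110.5,chi1-122
LEU,CG,CB,CA,N,1.530,116.3,chi1
LEU,CD1,CG,CB,CA,1.524,110.7,chi2
LEU,CD2,CG,CB,CA,1.525,110.7,chi2+122
ILE,CG1,CB,CA,N,1.530,110.4,chi1
ILE,CG2,CB,CA,N,1.521,110.5,chi1-122
ILE,CD1,CG1,CB,CA,1.513,113.8,chi2
MET,CG,CB,CA,N,1.520,114.1,chi1
MET,SD,CG,CB,CA,1.803,112.7,chi2
MET,CE,SD,CG,CB,1.791,100.9,chi3
PHE,CG,CB,CA,N,1.502,113.8,chi1
PHE,CD1,CG,CB,CA,1.384,120.8,chi2
PHE,CD2,CG,CB,CA,1.384,120.8,chi2+180
PHE,CE1,CD1,CG,CB,1.382,121.0,180
PHE,CE2,CD2,CG,CB,1.382,121.0,180
PHE,CZ,CE1,CD1,CG,1.382,120.0,0
TYR,CG,CB,CA,N,1.502,113.8,chi1
TYR,CD1,CG,CB,CA,1.384,120.8,chi2
TYR,CD2,CG,CB,CA,1.384,120.8,chi2+180
TYR,CE1,CD1,CG,CB,1.382,121.0,180
TYR,CE2,CD2,CG,CB,1.382,121.0,180
TYR,CZ,CE1,CD1,CG,1.382,120.0,0
TYR,OH,CZ,CE1,CD1,1.376,119.9,180
ASP,CG,CB,CA,N,1.516,113.0,chi1
ASP,OD1,CG,CB,CA,1.250,118.5,chi2
ASP,OD2,CG,CB,CA,1.250,118.5,chi2+180
ASN,CG,CB,CA,N,1.516,112.7,chi1
ASN,OD1,CG,CB,CA,1.231,120.8,chi2
ASN,ND2,CG,CB,CA,1.328,116.5,chi2+180
GLU,CG,CB,CA,N,1.530,114.1,chi1
GLU,CD,CG,CB,CA,1.516,112.6,chi2
GLU,OE1,CD,CG,CB,1.250,118.5,chi3
GLU,OE2,CD,CG,CB,1.250,118.5,chi3+180
GLN,CG,CB,CA,N,1.530,114.1,chi1
GLN,CD,CG,CB,CA,1.516,112.6,chi2
GLN,OE1,CD,CG,CB,1.231,120.8,chi3
GLN,NE2,CD,CG,CB,1.328,116.5,chi3+180
LYS,CG,CB,CA,N,1.520,114.1,chi1
LYS,CD,CG,CB,CA,1.520,111.3,chi2
LYS,CE,CD,CG,CB,1.520,111.3,chi3
LYS,NZ,CE,CD,CG,1.489,111.9,chi4
ARG,CG,CB,CA,N,1.520,114.1,chi1
ARG,CD,CG,CB,CA,1.520,111.3,chi2
ARG,NE,CD,CG,CB,1.461,112.0,chi3
ARG,CZ,NE,CD,CG,1.329,124.2,chi4
ARG,NH1,CZ,NE,CD,1.326,120.0,0
ARG,NH2,CZ,NE,CD,1.326,120.0,180
HIS,CG,CB,CA,N,1.497,113.8,chi1
HIS,ND1,CG,CB,CA,1.378,122.7,chi2
HIS,CD2,CG,CB,CA,1.354,131.1,chi2+180
HIS,CE1,ND1,CG,CB,1.320,109.3,180
HIS,NE2,CE1,ND1,CG,1.320,108.4,0
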