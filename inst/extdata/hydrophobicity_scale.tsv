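residue	sigma
ALA	-0.020
ARG	0.045
ASN	0.025
ASP	0.050
CYS	-0.025
GLN	0.022
GLU	0.048
GLY	-0.005
HIS	0.018
ILE	-0.038
LEU	-0.036
LYS	0.042
MET	-0.030
PHE	-0.040
PRO	0.010
SER	0.012
THR	0.008
TRP	-0.044
TYR	-0.015
VAL	-0.032
HPB	-0.040
PLB	0.030
CRT	-0.035
FE2	0.000
LIP	0.000
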