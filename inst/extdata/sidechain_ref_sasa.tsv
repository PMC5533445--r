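residue_name	ref_sasa
ALA	67
ARG	196
ASN	113
ASP	106
CYS	104
GLN	144
GLU	138
GLY	NA
HIS	151
ILE	140
LEU	137
LYS	167
MET	160
PHE	175
PRO	105
SER	80
THR	102
TRP	217
TYR	187
VAL	117
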