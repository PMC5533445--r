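residue_name	CA	CB	HA	C	N	H
ALA	52.5	19.1	4.32	177.8	123.8	8.24
ARG	56.0	30.9	4.34	176.3	120.5	8.23
ASN	53.1	38.9	4.74	175.2	118.7	8.40
ASP	54.2	41.1	4.64	176.3	120.4	8.34
CYS	58.2	28.0	4.55	174.6	118.8	8.32
GLN	55.7	29.4	4.34	176.0	119.8	8.32
GLU	56.6	29.9	4.35	176.6	120.2	8.42
GLY	45.1	NA	3.96	174.9	108.8	8.33
HIS	55.0	29.0	4.73	174.1	118.2	8.42
ILE	61.1	38.8	4.17	176.4	119.9	8.00
LEU	55.1	42.4	4.34	177.6	121.8	8.16
LYS	56.2	33.1	4.32	176.6	120.4	8.29
MET	55.4	32.9	4.48	176.3	119.6	8.28
PHE	57.7	39.6	4.62	175.8	120.3	8.30
PRO	63.3	32.1	4.42	177.3	128.1	NA
SER	58.3	63.8	4.47	174.6	115.7	8.31
THR	61.8	69.8	4.35	174.7	113.6	8.15
TRP	57.5	29.6	4.66	176.1	121.3	8.25
TYR	57.9	38.8	4.55	175.9	120.3	8.12
VAL	62.2	32.9	4.12	176.3	119.2	8.03
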