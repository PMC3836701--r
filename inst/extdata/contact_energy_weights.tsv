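# Per-residue contact-energy magnitudes (dimensionless) used to build the
# sequence-flavoring matrix as w_ij = sqrt(e_i * e_j), a one-parameter
# factorization of a statistical residue-residue contact potential
# (Miyazawa-Jernigan-style self-interaction magnitudes). version 1
res	e
ALA	2.72
ARG	3.41
ASN	2.51
ASP	2.41
CYS	5.44
GLN	2.79
GLU	2.91
GLY	2.24
HIS	3.77
ILE	6.54
LEU	7.04
LYS	1.95
MET	5.46
PHE	7.26
PRO	2.83
SER	2.52
THR	3.04
TRP	7.00
TYR	5.06
VAL	5.89
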