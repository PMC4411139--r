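restype pka sign charge_atoms
ASP 4.0 -1 OD1,OD2
GLU 4.4 -1 OE1,OE2
LYS 10.4 1 NZ
ARG 12.0 1 NH1,NH2
HIS 6.3 1 ND1,NE2
TYR 9.6 -1 OH
CYS 8.3 -1 SG
NTER 7.5 1 N
CTER 3.8 -1 O,OXT
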