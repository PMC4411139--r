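# United-atom radii (A) and neutral-form partial charges (e).
# Backbone: N/CA/C/O identical across residues; each neutral residue sums to 0.
# OXT is parameterized uncharged; terminal ionization charge is applied by the
# titratable-site model, not the parameter table.
res atom radius charge
ALA N 1.625 -0.40
ALA CA 1.90 0.40
ALA C 1.90 0.45
ALA O 1.48 -0.45
ALA CB 1.90 0.00
GLY N 1.625 -0.40
GLY CA 1.90 0.40
GLY C 1.90 0.45
GLY O 1.48 -0.45
SER N 1.625 -0.40
SER CA 1.90 0.40
SER C 1.90 0.45
SER O 1.48 -0.45
SER CB 1.90 0.25
SER OG 1.48 -0.25
THR N 1.625 -0.40
THR CA 1.90 0.40
THR C 1.90 0.45
THR O 1.48 -0.45
THR CB 1.90 0.25
THR OG1 1.48 -0.25
THR CG2 1.90 0.00
CYS N 1.625 -0.40
CYS CA 1.90 0.40
CYS C 1.90 0.45
CYS O 1.48 -0.45
CYS CB 1.90 0.19
CYS SG 1.85 -0.19
VAL N 1.625 -0.40
VAL CA 1.90 0.40
VAL C 1.90 0.45
VAL O 1.48 -0.45
VAL CB 1.90 0.00
VAL CG1 1.90 0.00
VAL CG2 1.90 0.00
LEU N 1.625 -0.40
LEU CA 1.90 0.40
LEU C 1.90 0.45
LEU O 1.48 -0.45
LEU CB 1.90 0.00
LEU CG 1.90 0.00
LEU CD1 1.90 0.00
LEU CD2 1.90 0.00
ILE N 1.625 -0.40
ILE CA 1.90 0.40
ILE C 1.90 0.45
ILE O 1.48 -0.45
ILE CB 1.90 0.00
ILE CG1 1.90 0.00
ILE CG2 1.90 0.00
ILE CD1 1.90 0.00
MET N 1.625 -0.40
MET CA 1.90 0.40
MET C 1.90 0.45
MET O 1.48 -0.45
MET CB 1.90 0.00
MET CG 1.90 0.06
MET SD 1.85 -0.12
MET CE 1.90 0.06
PRO N 1.625 -0.40
PRO CA 1.90 0.40
PRO C 1.90 0.45
PRO O 1.48 -0.45
PRO CB 1.90 0.00
PRO CG 1.90 0.00
PRO CD 1.90 0.00
PHE N 1.625 -0.40
PHE CA 1.90 0.40
PHE C 1.90 0.45
PHE O 1.48 -0.45
PHE CB 1.90 0.00
PHE CG 1.90 0.00
PHE CD1 1.90 0.00
PHE CD2 1.90 0.00
PHE CE1 1.90 0.00
PHE CE2 1.90 0.00
PHE CZ 1.90 0.00
TYR N 1.625 -0.40
TYR CA 1.90 0.40
TYR C 1.90 0.45
TYR O 1.48 -0.45
TYR CB 1.90 0.00
TYR CG 1.90 0.00
TYR CD1 1.90 0.00
TYR CD2 1.90 0.00
TYR CE1 1.90 0.00
TYR CE2 1.90 0.00
TYR CZ 1.90 0.25
TYR OH 1.48 -0.25
TRP N 1.625 -0.40
TRP CA 1.90 0.40
TRP C 1.90 0.45
TRP O 1.48 -0.45
TRP CB 1.90 0.00
TRP CG 1.90 0.00
TRP CD1 1.90 0.00
TRP CD2 1.90 0.00
TRP NE1 1.625 -0.30
TRP CE2 1.90 0.30
TRP CE3 1.90 0.00
TRP CZ2 1.90 0.00
TRP CZ3 1.90 0.00
TRP CH2 1.90 0.00
ASN N 1.625 -0.40
ASN CA 1.90 0.40
ASN C 1.90 0.45
ASN O 1.48 -0.45
ASN CB 1.90 0.00
ASN CG 1.90 0.55
ASN OD1 1.48 -0.55
ASN ND2 1.625 0.00
GLN N 1.625 -0.40
GLN CA 1.90 0.40
GLN C 1.90 0.45
GLN O 1.48 -0.45
GLN CB 1.90 0.00
GLN CG 1.90 0.00
GLN CD 1.90 0.55
GLN OE1 1.48 -0.55
GLN NE2 1.625 0.00
ASP N 1.625 -0.40
ASP CA 1.90 0.40
ASP C 1.90 0.45
ASP O 1.48 -0.45
ASP CB 1.90 0.00
ASP CG 1.90 0.55
ASP OD1 1.48 -0.50
ASP OD2 1.48 -0.05
GLU N 1.625 -0.40
GLU CA 1.90 0.40
GLU C 1.90 0.45
GLU O 1.48 -0.45
GLU CB 1.90 0.00
GLU CG 1.90 0.00
GLU CD 1.90 0.55
GLU OE1 1.48 -0.50
GLU OE2 1.48 -0.05
LYS N 1.625 -0.40
LYS CA 1.90 0.40
LYS C 1.90 0.45
LYS O 1.48 -0.45
LYS CB 1.90 0.00
LYS CG 1.90 0.00
LYS CD 1.90 0.00
LYS CE 1.90 0.30
LYS NZ 1.625 -0.30
ARG N 1.625 -0.40
ARG CA 1.90 0.40
ARG C 1.90 0.45
ARG O 1.48 -0.45
ARG CB 1.90 0.00
ARG CG 1.90 0.00
ARG CD 1.90 0.00
ARG NE 1.625 -0.10
ARG CZ 1.90 0.50
ARG NH1 1.625 -0.20
ARG NH2 1.625 -0.20
HIS N 1.625 -0.40
HIS CA 1.90 0.40
HIS C 1.90 0.45
HIS O 1.48 -0.45
HIS CB 1.90 0.00
HIS CG 1.90 0.10
HIS ND1 1.625 -0.40
HIS CD2 1.90 0.10
HIS CE1 1.90 0.60
HIS NE2 1.625 -0.40
CAG C 1.90 0.00
SPH X 2.00 0.00
ANY OXT 1.48 0.00
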