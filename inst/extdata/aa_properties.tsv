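aa	name	kd_scale	charge
A	Ala	1.8	0
R	Arg	-4.5	1
N	Asn	-3.5	0
D	Asp	-3.5	-1
C	Cys	2.5	0
Q	Gln	-3.5	0
E	Glu	-3.5	-1
G	Gly	-0.4	0
H	His	-3.2	1
I	Ile	4.5	0
L	Leu	3.8	0
K	Lys	-3.9	1
M	Met	1.9	0
F	Phe	2.8	0
P	Pro	-1.6	0
S	Ser	-0.8	0
T	Thr	-0.7	0
W	Trp	-0.9	0
Y	Tyr	-1.3	0
V	Val	4.2	0
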