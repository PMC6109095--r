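aa	mass	buried	volume	polarity	charge	hydrophobicity	helix_propensity
A	71.0788	38	67	10.0	0	14.0	0.0
R	156.1875	1	148	15.5	1	1.0	0.21
N	114.1038	12	96	18.0	0	4.5	0.65
D	115.0886	15	91	20.0	-1	4.5	0.69
C	103.1388	47	86	5.0	0	16.0	0.68
Q	128.1307	7	114	15.5	0	4.5	0.39
E	129.1155	18	109	19.0	-1	4.5	0.4
G	57.0519	37	48	12.0	0	13.0	1.0
H	137.1411	19	118	14.0	0	7.0	0.61
I	113.1594	65	124	2.5	0	20.0	0.41
L	113.1594	41	124	1.0	0	18.0	0.21
K	128.1741	3	135	17.0	1	2.0	0.26
M	131.1926	50	124	6.0	0	15.0	0.24
F	147.1766	48	135	2.5	0	17.0	0.54
P	97.1167	24	90	9.0	0	8.0	3.16
S	87.0782	24	73	13.0	0	11.0	0.5
T	101.1051	25	93	11.0	0	12.0	0.66
W	186.2132	23	163	4.0	0	10.0	0.49
Y	163.176	13	141	8.0	0	9.0	0.53
V	99.1326	56	105	7.0	0	19.0	0.61
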