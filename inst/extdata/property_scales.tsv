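residue	SoA	Hyd	Mass	Hyp	Pol	vdW	ToA	IEP
A	1	1.8	71.0788	0.31	0.046	1.00	1.42	6.00
C	2	2.5	103.1388	1.54	0.128	2.43	0.70	5.07
D	3	-3.5	115.0886	-0.77	0.105	2.78	1.01	2.77
E	4	-3.5	129.1155	-0.64	0.151	3.78	1.51	3.22
F	5	2.8	147.1766	1.79	0.290	5.89	1.13	5.48
G	6	-0.4	57.0519	0.00	0.000	0.00	0.57	5.97
H	7	-3.2	137.1411	0.13	0.230	4.66	1.00	7.59
I	8	4.5	113.1594	1.80	0.186	4.00	1.08	6.02
K	9	-3.9	128.1741	-0.99	0.219	4.77	1.16	9.74
L	10	3.8	113.1594	1.70	0.186	4.00	1.21	5.98
M	11	1.9	131.1926	1.23	0.221	4.43	1.45	5.74
N	12	-3.5	114.1038	-0.60	0.134	2.95	0.67	5.41
P	13	-1.6	97.1167	0.72	0.131	2.72	0.57	6.30
Q	14	-3.5	128.1307	-0.22	0.180	3.95	1.11	5.65
R	15	-4.5	156.1875	-1.01	0.291	6.13	0.98	10.76
S	16	-0.8	87.0782	-0.04	0.062	1.60	0.77	5.68
T	17	-0.7	101.1051	0.26	0.108	2.60	0.83	5.60
V	18	4.2	99.1326	1.22	0.140	3.00	1.06	5.96
W	19	-0.9	186.2132	2.25	0.409	8.08	1.08	5.89
Y	20	-1.3	163.1760	0.96	0.298	6.47	0.69	5.66
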