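aa	z1	z2	z3
A	0.72	2.48	1.42
C	2.11	2.74	-3.84
D	-6.04	0.03	-0.18
E	-5.70	0.34	-1.46
F	7.18	-1.53	0.05
G	-0.76	3.08	1.21
H	-2.55	-1.00	-1.94
I	6.65	0.29	0.04
K	-6.68	-1.32	1.16
L	6.59	-0.20	1.17
M	4.14	-0.43	-1.46
N	-4.35	0.21	0.30
P	-0.03	-0.36	1.87
Q	-3.97	-0.47	0.15
R	-6.30	-2.93	-0.91
S	-2.65	1.84	1.30
T	-1.42	0.80	0.94
V	4.79	1.98	-0.35
W	5.68	-3.50	0.16
Y	2.58	-2.06	0.37
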