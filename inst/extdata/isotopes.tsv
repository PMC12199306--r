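symbol	atomic_number	most_common_mass_number
H	1	1
He	2	4
Li	3	7
Be	4	9
B	5	11
C	6	12
N	7	14
O	8	16
F	9	19
Ne	10	20
Na	11	23
Mg	12	24
Al	13	27
Si	14	28
P	15	31
S	16	32
Cl	17	35
Ar	18	40
K	19	39
Ca	20	40
Sc	21	45
Ti	22	48
V	23	51
Cr	24	52
Mn	25	55
Fe	26	56
Co	27	59
Ni	28	58
Cu	29	63
Zn	30	64
Ga	31	69
Ge	32	74
As	33	75
Se	34	80
Br	35	79
Kr	36	84
Rb	37	85
Sr	38	88
Y	39	89
Zr	40	90
Nb	41	93
Mo	42	98
Tc	43	97
Ru	44	102
Rh	45	103
Pd	46	106
Ag	47	107
Cd	48	114
In	49	115
Sn	50	120
Sb	51	121
Te	52	130
I	53	127
Xe	54	132
Cs	55	133
Ba	56	138
La	57	139
Ce	58	140
Pr	59	141
Nd	60	142
Pm	61	145
Sm	62	152
Eu	63	153
Gd	64	158
Tb	65	159
Dy	66	164
Ho	67	165
Er	68	166
Tm	69	169
Yb	70	174
Lu	71	175
Hf	72	180
Ta	73	181
W	74	184
Re	75	187
Os	76	192
Ir	77	193
Pt	78	195
Au	79	197
Hg	80	202
Tl	81	205
Pb	82	208
Bi	83	209
Po	84	209
At	85	210
Rn	86	222
Fr	87	223
Ra	88	226
Ac	89	227
Th	90	232
Pa	91	231
U	92	238
Np	93	236
Pu	94	238
Am	95	241
Cm	96	243
Bk	97	247
Cf	98	249
Es	99	252
Fm	100	257
Md	101	258
No	102	259
Lr	103	262
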