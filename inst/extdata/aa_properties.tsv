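aa	alpha_propensity	beta_propensity	coil_propensity	aromaticity	branchness	bulkiness	charge	dG_octanol_water	flexibility	hydrophobicity	logD	molecular_weight	mutability	pI	polarity	polarity2	vdw_volume	consensus_hydrophobicity
A	1.42	0.83	0.66	0	0	11.50	0	0.31	0.357	1.8	0.31	89.09	100	6.00	8.1	0.00	67	0.62
R	0.98	0.93	0.95	0	0	14.28	1	-1.01	0.529	-4.5	-3.01	174.20	65	10.76	10.5	52.00	148	-2.53
N	0.67	0.89	1.56	0	0	12.82	0	-0.60	0.463	-3.5	-0.60	132.12	134	5.41	11.6	3.38	96	-0.78
D	1.01	0.54	1.46	0	0	11.68	-1	-0.77	0.511	-3.5	-2.77	133.10	106	2.77	13.0	49.70	91	-0.90
C	0.70	1.19	1.19	0	0	13.46	0	1.54	0.346	2.5	1.54	121.16	20	5.07	5.5	1.48	86	0.29
Q	1.11	1.10	0.98	0	0	14.45	0	-0.22	0.493	-3.5	-0.22	146.15	93	5.65	10.5	3.53	114	-0.85
E	1.51	0.37	0.74	0	0	13.57	-1	-0.64	0.497	-3.5	-2.64	147.13	102	3.22	12.3	49.90	109	-0.74
G	0.57	0.75	1.56	0	0	3.40	0	0.00	0.544	-0.4	0.00	75.07	49	5.97	9.0	0.00	48	0.48
H	1.00	0.87	0.95	1	0	13.69	0	0.13	0.323	-3.2	0.13	155.16	66	7.59	10.4	51.60	118	-0.40
I	1.08	1.60	0.47	0	1	21.40	0	1.80	0.462	4.5	1.80	131.17	96	6.02	5.2	0.13	124	1.38
L	1.21	1.30	0.59	0	0	21.40	0	1.70	0.365	3.8	1.70	131.17	40	5.98	4.9	0.13	124	1.06
K	1.16	0.74	1.01	0	0	15.71	1	-0.99	0.466	-3.9	-2.99	146.19	56	9.74	11.3	49.50	135	-1.50
M	1.45	1.05	0.60	0	0	16.25	0	1.23	0.295	1.9	1.23	149.21	94	5.74	5.7	1.43	124	0.64
F	1.13	1.38	0.60	1	0	19.80	0	1.79	0.314	2.8	1.79	165.19	41	5.48	5.2	0.35	135	1.19
P	0.57	0.55	1.52	0	0	17.43	0	0.72	0.509	-1.6	0.72	115.13	56	6.30	8.0	1.58	90	0.12
S	0.77	0.75	1.43	0	0	9.47	0	-0.04	0.507	-0.8	-0.04	105.09	120	5.68	9.2	1.67	73	-0.18
T	0.83	1.19	0.96	0	1	15.77	0	0.26	0.444	-0.7	0.26	119.12	97	5.60	8.6	1.66	93	-0.05
W	1.08	1.37	0.96	1	0	21.67	0	2.25	0.305	-0.9	2.25	204.23	18	5.89	5.4	2.10	163	0.81
Y	0.69	1.47	1.14	1	0	18.03	0	0.96	0.420	-1.3	0.96	181.19	41	5.66	6.2	1.61	141	0.26
V	1.06	1.70	0.50	0	1	21.57	0	1.22	0.386	4.2	1.22	117.15	74	5.96	5.9	0.13	105	1.08
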