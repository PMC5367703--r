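Subtype	ID	Sex	Blast Rate (%)	Age (months)	DNA Index	Karyotype	Prognostic Risk Group	Events	DFCI Protocol
HHD	315	F	98	127	1.12		High	R	95-01
HHD	327	M	98.5	72	1.13		Standard		95-01
HHD	39	M	-	49	1.14		Standard		91-01
HHD	442	M	95.5	48	1.12	4,6,21,X	High		2000-01
HHD	659	M	99.5	35	1.16	2,4,6,10,14,18,21,X 3?	High	R	2000-01
HHD	670	M	92.5	33	1.2	2,4,6,9,10,14,17,21,X	High	R	2000-01
HHD	777	F	89	33	1.15	4,6,10,14,17,21	High		2005-01
HHD	801	M	93	48	1.17	4,6,8,10,14,17,18,21,X	High		2005-01
HHD	813	F	74	51	1.18	4,5,6,10,14,17,21,X	Standard		2005-01
HHD	819	M	97	48	1.12	4,6,14,21	High		2005-01
HHD	826	F	50.2	13	1.25	4,5,6,7,8,10,11,12,14,15,17,21,22	Standard		2005-01
Other	399	M	96.5	43	1	8,X	Standard	R,D	95-01
Other	41	M	-	127	1.07		High		91-01
Other	419	M	93.5	172	1	None	High		2000-01
Other	436	F	94.5	99	1	None	Standard		2000-01
Other	446	F	90.5	106	-	None	High		2000-01
Other	447	F	97.5	129	1	21c	High	R,D	2000-01
Other	553	M	99.4	81	1	None	Standard		2000-01
Other	579	M	95.5	75	1	None	High	R,D	2000-01
Other	580	F	97	52	1		Standard		2000-01
Other	595	M	97	155	1	5	High	R,D	2000-01
Other	596	F	96.5	22	1	None	Standard		2000-01
Other	599	M	100	88	1	None	High		2000-01
Other	608	M	83	47	1	None	High		2000-01
Other	617	F	93	46	1		Standard		2000-01
Other	720	F	94.5	37	1	None	Standard	R,D	2005-01
Other	756	F	92.5	30	1	None	High		2005-01
Other	757	F	96.5	127	1	None	High		2005-01
Other	794	M	100	168	1		High		2005-01
Other	831	F	91	187	1	X	High		2005-01
t(12;21)	220	M	92.5	69	1		High		95-01
t(12;21)	373	F	97.5	55	1		High		95-01
t(12;21)	392	M	97	84	1	None	Standard		95-01
t(12;21)	411	F	86.8	57	1	None	Standard		95-01
t(12;21)	413	F	83.2	40	1	None	Standard		2000-01
t(12;21)	420	M	97.5	57	1		High		2000-01
t(12;21)	443	F	99.5	32	1	None	High		2000-01
t(12;21)	5	M	-	63	1		Standard		91-01
t(12;21)	614	F	96	48	1	None	High		2000-01
t(12;21)	676	F	93	43	1		Standard		2000-01
t(12;21)	691	M	97.5	30	1		Standard		2005-01
t(12;21)	696	F	98	51	1		Very High		2005-01
t(12;21)	73	F	-	78	1		Standard		95-01
t(12;21)	732	F	96	33	1	None	Standard		2005-01
t(12;21)	753	F	95	61	1	None	Standard		2005-01
t(12;21)	814	F	93	107	1	None	High	R,D	2005-01
t(12;21)	817	F	93	67	1	None	Standard		2005-01
t(12;21)	824	M	87	66	1	None	Standard		2005-01
t(12;21)	827	M	76.5	45	1	21	High		2005-01
t(12;21)	832	M	98.5	61	1		Standard		2005-01
t(12;21)	854	F	91.5	31	1	None	Standard		2005-01
t(12;21)	856	M	92	30	1	None	Standard		2005-01
t(9;22)	485	M	96.4	77	1	None	High	R,D	2000-01
t(9;22)	697	M	96	113	1	None	High	D	2005-01
t(9;22)	790	M	88.5	171	1	Not enough information	High	R	-
t(9;22)	825	F	91	138	1	None	High		2005-01
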