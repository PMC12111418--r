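Number	Genes	Location (bp)	Size (bp)	Intergenic Spacer (bp)	Coding Strand	Start Codon	Stop Codon
1	tRNA-Phe	1–69	69	0	H
2	12S rRNA	70–1025	956	0	H
3	tRNA-Val	1026–1097	72	0	H
4	16S rRNA	1098–2781	1684	0	H
5	tRNA-Leu	2782–2857	76	0	H
6	ND1	2858–3832	975	6	H	ATG	TAA
7	tRNA-Ile	3839–3909	71	-2	H
8	tRNA-Gln	3978–3908	71	3	L
9	tRNA-Met	3982–4050	69	0	H
10	ND2	4051–5095	1045	0	H	ATG	T--
11	tRNA-Trp	5096–5165	70	2	H
12	tRNA-Ala	5237–5168	70	1	L
13	tRNA-Asn	5311–5239	73	33	L
14	tRNA-Cys	5411–5345	67	-1	L
15	tRNA-Tyr	5481–5411	71	1	L
16	COX1	5483–7033	1551	0	H	GTG	TAA
17	tRNA-Ser	7104–7034	71	5	L
18	tRNA-Asp	7110–7179	70	13	H
19	COX2	7193–7883	691	0	H	ATG	T--
20	tRNA-Lys	7884–7959	76	1	H
21	ATP8	7961–8125	165	-7	H	ATG	TAG
22	ATP6	8119–8802	684	-1	H	ATG	TAA
23	COX3	8802–9586	785	0	H	ATG	TA-
24	tRNA-Gly	9587–9659	73	0	H
25	ND3	9660–10,008	349	0	H	ATG	T--
26	tRNA-Arg	10,009–10,079	71	0	H
27	ND4L	10,080–10,376	297	-7	H	ATG	TAA
28	ND4	10,370–11,750	1381	0	H	ATG	T--
29	tRNA-His	11,751–11,819	69	0	H
30	tRNA-Ser	11,820–11,888	69	1	H
31	tRNA-Leu	11,890–11,962	73	0	H
32	ND5	11,963–13,786	1824	-4	H	ATG	TAA
33	ND6	14,304–13,783	522	0	L	ATG	TAA
34	tRNA-Glu	14,373–14,305	69	5	L
35	CYTB	14,379–15,519	1141	0	H	ATG	T--
36	tRNA-Thr	15,520–15,591	72	-1	H
37	tRNA-Pro	15,661–15,591	71	0	L
38	D-loop	15,662–16,606	945	0	H
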