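amino_acid	mass_percent	mw	precursor
Ala	10.17	89.09	pyr
Cys	1.56	121.16	pyr
Asp	6.89	133.10	oaa
Glu	3.91	147.13	oaa
Phe	3.44	165.19	p5p
Gly	7.20	75.07	pyr
His	0.63	155.15	p5p
Ile	3.76	131.17	oaa
Lys	2.03	146.19	oaa
Leu	7.51	131.17	pyr
Met	0.47	149.21	oaa
Asn	3.91	132.12	oaa
Pro	3.44	115.13	oaa
Gln	2.66	146.15	oaa
Arg	3.13	174.20	oaa
Ser	13.77	105.09	pyr
Thr	11.58	119.12	oaa
Val	6.57	117.15	pyr
Trp	3.13	204.23	p5p
Tyr	4.23	181.19	p5p
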