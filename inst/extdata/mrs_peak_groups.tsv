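# Default grouping of liver 1H-MRS lipid resonances into saturated (fSL),
# mono-unsaturated (fMUL) and poly-unsaturated (fPUL) signal fractions.
# Labels follow the LipXX convention (chemical shift x10 in ppm); the
# assignment by shift is approximate and meant to be edited per acquisition.
label	ppm	assignment	fraction
Lip09	0.90	methyl -CH3	fSL
Lip13	1.30	methylene -(CH2)n-	fSL
Lip16	1.60	beta-carboxyl -CH2-CH2-COO	fSL
Lip23	2.25	alpha-carboxyl -CH2-COO	fSL
Lip21	2.02	allylic -CH2-CH=CH-	fMUL
Lip53	5.30	olefinic -CH=CH-	fMUL
Lip28	2.80	diallylic =CH-CH2-CH=	fPUL
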