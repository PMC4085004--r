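Gene Name	Symbol	FC	p.value
ATP-binding cassette, sub-family A (ABC1), member 8	Abca8a	1.17	7.17E-04
Aldo-keto reductase family 1 member B3	Akr1b3	1.29	6.88E-07
Ankyrin repeat domain 1 (cardiac muscle)	Ankrd1	1.67	2.55E-05
Electron-transfer-flavoprotein, beta polypeptide	Etfb	-1.10	7.49E-04
Fc fragment of IgG, low affinity IIIb, receptor (CD16b)	Fcgr3	1.23	3.20E-04
Fumarylacetoacetate hydrolase domain containing 1	Fahd1	1.15	1.05E-04
Flt3-interacting zinc finger protein	Fiz1	-1.11	5.29E-06
growth arrest-specific 6	Gas6	1.13	4.80E-05
Growth differentiation factor 15	Gdf15	1.73	9.05E-05
Heat shock 27kDa protein 1	Hspb1	1.09	8.78E-04
Lipocalin 2	Lcn2	1.75	8.75E-05
Natriuretic peptide A	Nppa	2.10	1.37E-05
Protein kinase (cAMP-dependent, catalytic) inhibitor alpha	Pkia	-1.10	9.53E-04
Protein kinase C, delta	Prkcd	1.24	5.12E-07
Prolactin receptor	Prlr	-1.35	3.99E-06
Prostaglandin D2 synthase 21kDa (brain)	Ptgds	1.48	2.15E-04
RAB31, member RAS oncogene family	Rab31	1.27	3.87E-05
Retinal outer segment membrane protein 1	Rom1	1.26	2.63E-05
Solute carrier family 19 (thiamine transporter), member 2	Slc19a2	1.29	1.58E-05
Solute carrier family 7 (orphan transporter), member 4	Slc7a4	1.17	4.59E-04
Single-stranded DNA binding protein 2	Ssbp2	-1.40	3.07E-04
Sushi, von Willebrand factor type A, EGF and pentraxin domain containing 1	Svep1	1.26	2.82E-04
Tetraspanin 17	Tspan17	1.26	6.30E-05
WNT1 inducible signaling pathway protein 2	Wisp2	1.38	4.74E-04
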