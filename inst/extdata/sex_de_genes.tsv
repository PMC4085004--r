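Gene Name	Symbol	FC	p.value
Branched chain amino-acid transaminase 1, cytosolic	Bcat1	-1.20	3.09E-05
Fumarylacetoacetate hydrolase (fumarylacetoacetase)	Fah	-1.26	1.77E-04
Glycosyltransferase 8 domain containing	Glt8d1	1.14	1.34E-04
Immunoglobulin superfamily, member 1	Igsf1	-1.32	1.08E-04
Cytochrome P450, family 27, subfamily A, polypeptide	Cyp27a1	-1.20	1.60E-04
Guanylate cyclase 1, soluble, alpha 3	Gucy1a3	1.37	1.57E-04
Hydroxyacylglutathione hydrolase-like	Haghl	-1.21	1.94E-04
Coenzyme Q5 homolog, methyltransferase	Coq5	-1.11	9.35E-05
Eotaxin	Ccl11	-1.75	1.02E-05
Bone morphogenetic protein-binding endothelial cell precursor-derived regulator	Bmper	-1.38	1.68E-04
Hydroxysteroid (11-beta) dehydrogenase 1	Hsd11b1	-2.40	1.50E-08
Collagen, type XIV, alpha	Col14a1	1.31	6.32E-05
DEAD (Asp-Glu-Ala-Asp) box polypeptide 3, Y-linked	Ddx3y	-16.45	7.96E-16
DIRAS family, GTP-binding RAS-like	Diras2	1.20	1.91E-04
Chemokine (C-X-C motif) ligand	Cxcl14	-1.68	1.42E-06
DnaJ (Hsp40) homolog, subfamily C, member 30	Dnajc30	-1.07	1.13E-05
Eukaryotic translation elongation factor 1 delta	Eef1d	1.10	1.46E-04
Eukaryotic translation initiation factor 2, subunit 3 gamma, 52kDa pseudogene	Eif2s3x	1.59	3.08E-07
Eukaryotic translation initiation factor 2, subunit 3 gamma, 52kDa pseudogene	Eif2s3y	-9.75	9.63E-14
Eukaryotic translation initiation factor 4E family member 3	Eif4e3	-1.14	1.13E-04
Elastin microfibril interfacer 2	Emilin2	1.20	2.43E-04
Guanine nucleotide binding protein (G protein), gamma 8	Gng8	1.33	2.33E-04
Golgi SNAP receptor complex member 2	Gosr2	-1.12	8.56E-05
G protein-coupled receptor associated sorting protein 1	Gprasp1	1.22	1.50E-04
Indolethylamine N-methyltransferase	Inmt	-2.23	8.35E-05
Potassium voltage-gated channel, Isk-related family, member 1	Kcne1	2.32	1.04E-04
Kinesin family member 3C	Kif3c	1.14	1.18E-04
Kallikrein 1-related petidase b26	Klk1b26	-1.34	1.46E-04
Lysyl oxidase	Lox	-1.40	2.20E-04
Keratan sulfate proteoglycan lumican	Lum	1.48	1.94E-04
Myeloid differentiation protein-2	Ly96	-1.06	9.58E-05
Microspherule protein 1	Mcrs1	1.12	2.60E-04
Midkine (neurite growth-promoting factor 2)	Mdk	1.52	2.64E-06
Nidogen 1	Nid1	-1.20	1.17E-04
Organic solute transporter alpha	Osta	1.27	2.45E-05
Oviductal glycoprotein 1, 120kDa	Ovgp1	1.22	2.55E-05
Pleiotrophin	Ptn	1.78	3.82E-08
RAS-like, family 10, member B	Rasl10b	-1.27	5.37E-05
Ring finger protein 219	Rnf219	1.19	2.55E-05
Serpin peptidase inhibitor, clade A	Serpina3n	-2.57	1.60E-04
Solute carrier family 1 (glial high affinity glutamate transporter), member 3	Slc1a3	1.26	2.54E-04
Slowmo homolog 2 (Drosophila)	Slmo2	-1.10	1.38E-04
Sortilin 1	Sort1	1.22	6.28E-05
Vesicle-associated membrane protein 7	Sybl1	1.43	1.82E-06
Epicardin	Tcf21	1.27	2.55E-04
Tudor domain-containing protein 2	Tdrkh	1.21	2.57E-04
Transmembrane protein 141	Tmem141	-1.10	1.07E-04
Transmembrane protein 201	Tmem201	1.17	2.41E-05
Transmembrane protein 38A	Tmem38a	-1.14	9.36E-05
Transmembrane protein 82	Tmem82	1.35	5.97E-05
TruB pseudouridine (psi) synthase homolog 2	Trub2	-1.16	1.42E-04
Ubiquitin specific peptidase 18	Usp18	1.26	7.17E-05
Histone demethylase UTX	Utx	1.82	5.11E-07
Vesicle-associated membrane protein 4	Vamp4	1.14	1.37E-04
WNT1 inducible signaling pathway protein 2	Wisp2	-2.03	3.17E-07
X (inactive)-specific transcript (non-protein coding)	Xist	2.23	2.35E-08
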