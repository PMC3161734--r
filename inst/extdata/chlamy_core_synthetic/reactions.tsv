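reaction_id	equation	enzyme	ec	genes
R_PGI	1 G6P <-> 1 F6P	glucose-6-phosphate isomerase	5.3.1.9
R_PFKALD	1 F6P + 1 ATP -> 2 GAP + 1 ADP	phosphofructokinase/aldolase/triose-phosphate isomerase (lumped)	2.7.1.11
R_GLYC	1 GAP + 1 NAD + 2 ADP <-> 1 PYR + 1 NADH + 2 ATP	lower glycolysis / gluconeogenesis (lumped GAPDH..pyruvate kinase)	1.2.1.12
R_PDH	1 PYR + 1 COA + 1 NAD -> 1 ACCOA + 1 CO2 + 1 NADH	pyruvate dehydrogenase complex	1.2.4.1
R_ACS	1 ACE + 1 COA + 1 ATP -> 1 ACCOA + 1 ADP	acetyl-CoA synthetase	6.2.1.1
R_CS	1 ACCOA + 1 OAA -> 1 CIT + 1 COA	citrate synthase	2.3.3.1
R_ACO	1 CIT <-> 1 ICIT	aconitase	4.2.1.3
R_IDHNAD	1 ICIT + 1 NAD -> 1 AKG + 1 CO2 + 1 NADH	isocitrate dehydrogenase (NAD)	1.1.1.41
R_IDHNADP	1 ICIT + 1 NADP -> 1 AKG + 1 CO2 + 1 NADPH	isocitrate dehydrogenase (NADP)	1.1.1.42
R_AKGDH	1 AKG + 1 NAD + 1 ADP -> 1 SUCC + 1 CO2 + 1 NADH + 1 ATP	2-oxoglutarate dehydrogenase / succinyl-CoA synthetase (lumped)	1.2.4.2
R_SDH	1 SUCC + 1 NAD -> 1 FUM + 1 NADH	succinate dehydrogenase	1.3.5.1
R_FH	1 FUM <-> 1 MAL	fumarase	4.2.1.2
R_MDH	1 MAL + 1 NAD <-> 1 OAA + 1 NADH	malate dehydrogenase	1.1.1.37
R_ICL	1 ICIT -> 1 SUCC + 1 GLX	isocitrate lyase	4.1.3.1
R_MS	1 GLX + 1 ACCOA -> 1 MAL + 1 COA	malate synthase	2.3.3.9
R_PPPOX	1 G6P + 2 NADP -> 1 RU5P + 1 CO2 + 2 NADPH	oxidative pentose phosphate pathway (lumped G6PDH/6PGD)	1.1.1.49
R_PPPNOX	3 RU5P <-> 2 F6P + 1 GAP	non-oxidative pentose phosphate pathway (lumped transketolase/transaldolase)	2.2.1.1
R_PYC	1 PYR + 1 CO2 + 1 ATP -> 1 OAA + 1 ADP	pyruvate carboxylase	6.4.1.1
R_ETC	1 NADH + 2 ADP -> 1 NAD + 2 ATP	electron transport chain (lumped, P/O = 2)
R_ATPM	1 ATP -> 1 ADP	ATP maintenance hydrolysis	3.6.1.3
R_TH	1 NADH + 1 NADP -> 1 NAD + 1 NADPH	transhydrogenase	1.6.1.2
R_FNR	1 NADPH + 2 FDOX <-> 1 NADP + 2 FDRED	ferredoxin-NADP+ reductase	1.18.1.2
R_NR	1 NO3 + 1 NADH -> 1 NO2I + 1 NAD	nitrate reductase	1.7.1.1
R_NO2T	1 NO2 -> 1 NO2I	nitrite uptake transporter	
R_NIR	1 NO2I + 6 FDRED -> 1 NH4 + 6 FDOX	nitrite reductase	1.7.7.1
R_GS	1 GLU + 1 NH4 + 1 ATP -> 1 GLN + 1 ADP	glutamine synthetase	6.3.1.2
R_GOGAT	1 GLN + 1 AKG + 2 FDRED -> 2 GLU + 2 FDOX	ferredoxin-glutamate synthase	1.4.7.1
R_GDH	1 AKG + 1 NH4 + 1 NADPH <-> 1 GLU + 1 NADP	glutamate dehydrogenase	1.4.1.4
R_ALT	1 PYR + 1 GLU -> 1 ALA + 1 AKG	alanine transaminase	2.6.1.2
R_AST	1 OAA + 1 GLU <-> 1 ASP + 1 AKG	aspartate transaminase	2.6.1.1
R_ASNS	1 ASP + 1 GLN + 1 ATP -> 1 ASN + 1 GLU + 1 ADP	asparagine synthetase	6.3.5.4
R_SERS	1 GAP + 1 NAD + 1 GLU -> 1 SER + 1 NADH + 1 AKG	phosphoserine pathway (lumped)	1.1.1.95
R_SHMT	1 SER -> 1 GLY + 1 C1	serine hydroxymethyltransferase	2.1.2.1
R_C1OX	1 C1 + 1 NAD -> 1 CO2 + 1 NADH	methylene-THF oxidation (lumped)	1.5.1.5
R_AGT	1 GLX + 1 GLU -> 1 GLY + 1 AKG	glyoxylate aminotransferase	2.6.1.4
R_LYSS	1 ASP + 1 PYR + 1 GLU + 2 NADPH + 1 ATP -> 1 LYS + 1 AKG + 1 CO2 + 2 NADP + 1 ADP	diaminopimelate pathway (lumped)	4.1.1.20
R_ORNS	2 GLU + 1 ATP + 1 NADPH -> 1 ORN + 1 AKG + 1 ADP + 1 NADP	ornithine synthesis (N-acetyl pathway, lumped)	2.6.1.11
R_CPS	1 CO2 + 1 NH4 + 2 ATP -> 1 CP + 2 ADP	carbamoyl-phosphate synthetase	6.3.4.16
R_OTC	1 ORN + 1 CP -> 1 CITR	ornithine transcarbamylase	2.1.3.3
R_ASS	1 CITR + 1 ASP + 2 ATP -> 1 ARGSUC + 2 ADP	argininosuccinate synthetase	6.3.4.5
R_ASL	1 ARGSUC -> 1 ARG + 1 FUM	argininosuccinate lyase	4.3.2.1
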