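# Transcribed competitive-inhibition and T-cell hybridoma response panels
# for glycopeptides 1-21 (1 = unmodified CII259-273 reference).
# aq_inhib_*/dr4_inhib_*: % inhibition of the biotinylated marker peptide at
# the stated competitor concentration (mean of replicates; SDs omitted).
# aq_active = FALSE marks designed peptides classified inactive (<30%
# inhibition) in a preliminary A(q) assay and not carried into the
# dose-dependent A(q) run (inhibition cells left NA, hybridomas n.d.).
# T-cell response categories: - none, + 150 uM, ++ 30 uM, +++ 6.0 uM,
# ++++ 1.2 uM, +++++ 0.24 uM, ++++++ 0.0064 uM, n.d. not determined
# (antigen concentration giving 10% of the max IL-2 response).
peptide	aq_active	aq_inhib_100	aq_inhib_500	tc_22a1_7E	tc_HCQ_3	tc_HCQ_10	tc_HM1R_2	tc_HD13_9	tc_HNC_1	dr4_inhib_100	dr4_inhib_500	tc_mDR17_2	tc_hDR11_2
1	TRUE	90	97	++++	+++++	++++	++++++	+++++	+++++	39	72	+++	+++
2	TRUE	87	95	++++	+++	+++	+++++	++++	++++	45	73	++++	++++
3	TRUE	28	59	+	+++	+	+++	++	++	41	65	++++	+++
4	TRUE	86	94	+++	+++++	++	+++++	++++	++	8	31	+++	-
5	TRUE	29	58	++	+	+	++	+++	++	49	77	+++++	++++
6	TRUE	46	75	-	-	+	++	-	-	62	84	+++++	+++
7	TRUE	39	67	+	+++	-	+++	++	++	10	34	+++	-
8	TRUE	55	78	+	+	+	+++	-	-	50	70	+++++	++++
9	TRUE	38	70	-	-	-	+	-	-	44	75	+++++	+++
10	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	20	19	++	-
11	TRUE	29	53	+	+	+	++	+	-	51	76	+++++	++++
12	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	48	73	++++	+++
13	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	22	52	+++	+
14	TRUE	20	50	+	+++	+	+++	++	-	46	74	++++	+++
15	TRUE	41	71	-	-	++	++	-	-	55	76	+++++	++++
16	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	18	23	+	-
17	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	20	26	++	-
18	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	47	60	+++	+++
19	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	37	80	+++	+++
20	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	62	82	++++	++
21	FALSE	NA	NA	n.d.	n.d.	n.d.	n.d.	n.d.	n.d.	44	84	++++	++++
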