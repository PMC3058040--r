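# Anchor-residue assignment of glycopeptides 1-21 (1 = unmodified reference).
# Pairs directly stated in the running SAR text are marked confirmed = TRUE;
# the remainder are provisional assignments chosen to respect the published
# constraints (each residue level present in >= 2 of the 20 designed
# peptides, unique pairs, inactive/weak-binder patterns per position).
peptide	p260	p263	p260_confirmed	p263_confirmed	designed
1	Ile	Phe	TRUE	TRUE	FALSE
2	Ile	Ffe	TRUE	TRUE	TRUE
3	Ile	Tyr	TRUE	TRUE	TRUE
4	Ile	Thz	TRUE	TRUE	TRUE
5	Hle	Ffe	TRUE	TRUE	TRUE
6	Hle	Cha	TRUE	TRUE	TRUE
7	Hle	Thz	TRUE	TRUE	TRUE
8	Chg	Mfe	FALSE	TRUE	TRUE
9	Cpa	Cha	TRUE	TRUE	TRUE
10	Thz	Pya	FALSE	TRUE	TRUE
11	Cpa	Mfe	FALSE	TRUE	TRUE
12	Chg	Tyr	TRUE	TRUE	TRUE
13	Gln	Pya	FALSE	TRUE	TRUE
14	Thz	Phe	TRUE	TRUE	TRUE
15	Thz	Mfe	TRUE	TRUE	TRUE
16	Chg	Pya	FALSE	TRUE	TRUE
17	Gln	Thz	FALSE	FALSE	TRUE
18	Gln	Phe	FALSE	FALSE	TRUE
19	Cpa	Tyr	FALSE	TRUE	TRUE
20	Aic	Cha	TRUE	FALSE	TRUE
21	Aic	Ffe	TRUE	FALSE	TRUE
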