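code	name	natural
Ile	isoleucine	TRUE
Hle	homoleucine	FALSE
Chg	cyclohexylglycine	FALSE
Cpa	cyclopropylalanine	FALSE
Thz	4-thiazolylalanine	FALSE
Gln	glutamine	TRUE
Aic	2-aminoindane-2-carboxylic acid	FALSE
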