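code	name	natural
Phe	phenylalanine	TRUE
Ffe	4-fluorophenylalanine	FALSE
Mfe	m-methylphenylalanine	FALSE
Cha	3-cyclohexylalanine	FALSE
Tyr	tyrosine	TRUE
Pya	4-pyridylalanine	FALSE
Thz	4-thiazolylalanine	FALSE
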