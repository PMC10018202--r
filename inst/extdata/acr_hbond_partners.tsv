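ligand_group	restype	count	share_pct
carbonyl	LYS	6	50.0
carbonyl	ARG	3	25.0
carbonyl	ASN	1	8.3
carbonyl	SER	1	8.3
carbonyl	TYR	1	8.3
amino	SER	NA	20.0
amino	HIS	NA	14.3
amino	TYR	NA	14.3
amino	ASP	NA	14.3
amino	THR	NA	14.3
amino	GLU	NA	14.3
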