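protein_id	protein	state	site	score_au	top_cluster_size	covalent	known_primary	score2_au	size2
HSA	Albumin		C34	-32.3	63	TRUE	TRUE	-31.3	69
CK	Creatine Kinase		C74	-21.3	12	FALSE	FALSE	NA	NA
CK	Creatine Kinase		C141	-31.7	63	TRUE	FALSE	NA	NA
CK	Creatine Kinase		C146	-28.2	22	TRUE	FALSE	NA	NA
CK	Creatine Kinase		C254	-23.3	34	TRUE	FALSE	NA	NA
CK	Creatine Kinase		C283	-32.8	61	TRUE	TRUE	NA	NA
D3R	Dopamine D3 Receptor		C114	-28.6	130	TRUE	TRUE	NA	NA
DAT	Dopamine Transporter	outward	C342	-2.0	21	TRUE	FALSE	NA	NA
DAT	Dopamine Transporter	inward	C135	-11.9	79	TRUE	FALSE	NA	NA
DAT	Dopamine Transporter	inward	C342	-15.1	87	TRUE	TRUE	NA	NA
GAPDH	Glyceraldehyde-3-phosphate dehydrogenase		C152	-12.3	163	TRUE	TRUE	NA	NA
GAPDH	Glyceraldehyde-3-phosphate dehydrogenase		C156	46.1	1	FALSE	FALSE	NA	NA
GAPDH	Glyceraldehyde-3-phosphate dehydrogenase		C247	9.9	14	FALSE	FALSE	NA	NA
HB	Hemoglobin		C93	-13.9	74	TRUE	TRUE	NA	NA
HB	Hemoglobin		C104	-3.3	75	FALSE	FALSE	NA	NA
NSF	NEM-sensitive factor		C264	-73.4	85	TRUE	TRUE	NA	NA
VATP	Vesicular proton ATPase		C254	-0.1	110	TRUE	TRUE	NA	NA
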