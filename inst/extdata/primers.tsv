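region	primer_id	role	fam	sequence
GWD-5p	GWD_F1	forward	FALSE	TTTGTATTGACTGATTTTGTATTGT
GWD-5p	GWD_R1	reverse	TRUE	TAGTTTCTAAGCCCCAAGCA
GWD-3p	GWD_F2	forward	FALSE	TCAGTCCAGTTGAAGCCGTTG
GWD-3p	GWD_R2	reverse	TRUE	TCACGAGTTCATTCATCTTTCCCA
DMR6-5p-ex1	DMR6_F1	forward	TRUE	CCATGGAAACGAAAGTTATTTC
DMR6-5p-ex1	DMR6_R1	reverse	FALSE	CAACCTAAGTCAATTATTGGAAC
DMR6-5p-ex2	DMR6_F2	forward	FALSE	AGCTGACCGGCAGCAAAATTGGGTAGCTGGGGAATTTTTCA
DMR6-5p-ex2	DMR6_R2	reverse	FALSE	GGTTACCATGCATAACTATACACAC
DMR6-5p-ex2	DMR6_FAM_tail	tail	TRUE	AGCTGACCGGCAGCAAAATTG
DMR6-5p-ex1+2	DMR6_R4	reverse	TRUE	CGATGGATTAGAAGGCCATTC
DMR6-3p	DMR6_F3	forward	FALSE	ATCGTGAGCAGATATTGCACG
DMR6-3p	DMR6_R3	reverse	TRUE	GGTTTACCTGCAATTGATCAC
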