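guide_id	gene	region	protospacer
gJ	GWD1	GWD-5p	TCAGTGGTAAGTACAGCATG
gK	GWD1	GWD-5p	AGGGAATAACTTGCTGTACC
gL	GWD1	GWD-5p	GTTTCGAGGTAACAGGTTAA
gM	GWD1	GWD-5p	GTACAGCAAGTTATTCCCTA
gA	GWD1	GWD-3p	GGAGAGGAGGAAATTCCTGA
gB	GWD1	GWD-3p	TGTTCGAGCTAGAAATGGGA
gC	GWD1	GWD-3p	GCTGACCTCCAAGCAAAGGA
gD	GWD1	GWD-3p	ATTGGCTGACCTCCAAGCAA
gE	GWD1	GWD-3p	TTTCTGTTCGAGCTAGAAAT
gI	GWD1	GWD-3p	CACAACGACAACATATCCAA
g43	DMR6-1	DMR6-5p	TTTGAGGGAGAGTAGAGTGG
g44	DMR6-1	DMR6-5p	GTGGCCTATCGGATTCGGGT
g45	DMR6-1	DMR6-5p	TGGAGAAATATGCTCCTGAA
g46	DMR6-1	DMR6-3p	GAAGCCATAGCAGAGAGCCT
g47	DMR6-1	DMR6-3p	GAATTTGGATCAGTATGGGC
g48	DMR6-1	DMR6-3p	ATCACCAAGATTAATGACAA
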